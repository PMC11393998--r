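# Shared synthetic fixtures, rendered once per test run.

.sceneCache <- new.env(parent = emptyenv())

defaultIntrinsics <- function() syntheticIntrinsics()

# default model rendered at the canonical 3 m side view
defaultScene <- function(distance = 3000) {
  key <- paste0("scene_", distance)
  if (is.null(.sceneCache[[key]])) {
    m <- cattleModel()
    p <- cameraPose(distance = distance)
    K <- defaultIntrinsics()
    img <- renderDepth(m, p, K)
    kps <- groundTruthKeypoints(m, p, K, img = img)
    .sceneCache[[key]] <- list(m = m, pose = p, K = K, img = img, kps = kps,
                               truth = measurementValues(trueDimensions(m)))
  }
  .sceneCache[[key]]
}

# flat wall at constant depth with all keypoints marked on it
flatWallScene <- function(depth = 3000, K = defaultIntrinsics()) {
  img <- depthImage(matrix(depth, K@height, K@width))
  kps <- keypointSet(list(Withers = c(500, 120), Sole = c(480, 600),
                          Shoulder = c(900, 300), Pin = c(200, 310),
                          Chest1 = c(700, 150), Chest2 = c(700, 460),
                          Lumbar = c(300, 140)))
  list(img = img, kps = kps, K = K)
}

# Ramanujan's second ellipse-perimeter approximation (independent oracle)
ramanujanPerimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

relErr <- function(x, ref) abs(x - ref) / abs(ref)
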