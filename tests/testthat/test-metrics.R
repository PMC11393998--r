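mkKps <- function(coords, vis = NULL, bbox = c(0, 0, 640, 360)) {
  keypointSet(coords, visibility = vis, bbox = bbox)
}

baseCoords <- function() {
  m <- rbind(Withers = c(500, 120), Sole = c(480, 600), Shoulder = c(820, 300),
             Pin = c(180, 310), Chest1 = c(700, 150), Chest2 = c(700, 460),
             Lumbar = c(300, 140))
  colnames(m) <- c("u", "v")
  m
}

test_that("OKS matches the closed form and a term-by-term oracle", {
  truth <- mkKps(baseCoords())
  expect_equal(oks(truth, truth), 1.0)
  # single visible landmark at distance S * sigma * sqrt(2) scores exp(-1)
  S <- bboxScale(c(0, 0, 640, 360))
  co <- baseCoords()
  vis1 <- stats::setNames(c(2L, rep(0L, 6)), landmarkNames())
  truth1 <- mkKps(co, vis = vis1)
  co2 <- co
  co2["Withers", ] <- co["Withers", ] + c(S * 0.05 * sqrt(2), 0)
  pred1 <- mkKps(co2)
  expect_equal(oks(pred1, truth1), exp(-1), tolerance = 1e-12)
  # random offsets against a brute-force evaluation of the formula
  set.seed(21)
  for (rep in 1:20) {
    off <- matrix(rnorm(14, 0, 30), 7, 2)
    pred <- mkKps(co + off)
    sig <- runif(7, 0.02, 0.1)
    p <- oksParams(scale = S, sigmas = stats::setNames(sig, landmarkNames()))
    brute <- mean(exp(-rowSums(off^2) / (2 * S^2 * sig^2)))
    expect_equal(oks(pred, truth, p), brute, tolerance = 1e-12)
  }
})

test_that("OKS counts obscured landmarks and rejects empty truth", {
  co <- baseCoords()
  vis <- stats::setNames(c(2L, 1L, 2L, 2L, 2L, 2L, 0L), landmarkNames())
  truth <- mkKps(co, vis = vis)
  pred <- mkKps(co)
  expect_equal(oks(pred, truth), 1.0)      # v = 1 still contributes
  # moving only the unmarked landmark leaves the score untouched
  co3 <- co; co3["Lumbar", ] <- co3["Lumbar", ] + 500
  expect_equal(oks(mkKps(co3), truth), 1.0)
  allHidden <- mkKps(co, vis = stats::setNames(rep(0L, 7), landmarkNames()))
  expect_error(oks(pred, allHidden), "undefined OKS")
})

test_that("OKS decreases monotonically as one landmark drifts", {
  truth <- mkKps(baseCoords())
  drift <- c(0, 5, 20, 50, 120)
  scores <- vapply(drift, function(d) {
    co <- baseCoords(); co["Pin", ] <- co["Pin", ] + c(d, 0)
    oks(mkKps(co), truth)
  }, numeric(1))
  expect_true(all(diff(scores) < 0 | drift[-1] == 0))
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("average precision uses a strict threshold", {
  expect_equal(averagePrecision(c(0.6, 0.4)), 0.5)
  expect_equal(averagePrecision(0.5), 0)        # at the threshold: false positive
  expect_equal(averagePrecision(rep(1, 5)), 1)
  expect_error(averagePrecision(numeric(0)), "no OKS")
  set.seed(4)
  x <- runif(50)
  expect_equal(averagePrecision(x), sum(x > 0.5) / 50, tolerance = 1e-15)
})

test_that("mean AP averages per-category values", {
  expect_equal(meanAP(0.9), 0.9)
  expect_equal(meanAP(c(1, 0)), 0.5)
  set.seed(6)
  x <- runif(13)
  expect_equal(meanAP(x), sum(x) / 13, tolerance = 1e-15)
  expect_error(meanAP(numeric(0)), "no AP")
})

test_that("precision and recall follow the count definitions", {
  expect_equal(precisionRecall(10, 0, 0), c(precision = 1, recall = 1))
  expect_equal(precisionRecall(5, 5, 15), c(precision = 0.5, recall = 0.25))
  expect_error(precisionRecall(0, 0, 3), "undefined precision")
  expect_error(precisionRecall(0, 3, 0), "undefined recall")
  expect_error(precisionRecall(-1, 3, 1), ">= 0")
})

test_that("MAE and MRE match brute-force loops and scale as expected", {
  expect_equal(mae(110, 100), 10)
  expect_equal(mre(110, 100), 10)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(8)
  for (rep in 1:10) {
    ref <- runif(17, 50, 200); est <- ref + rnorm(17, 0, 10)
    bruteMae <- 0; bruteMre <- 0
    for (i in 1:17) {
      bruteMae <- bruteMae + abs(est[i] - ref[i])
      bruteMre <- bruteMre + abs(est[i] - ref[i]) / ref[i]
    }
    expect_equal(mae(est, ref), bruteMae / 17, tolerance = 1e-12)
    expect_equal(mre(est, ref), 100 * bruteMre / 17, tolerance = 1e-12)
    # MRE is invariant under common rescaling; MAE scales linearly
    expect_equal(mre(7 * est, 7 * ref), mre(est, ref), tolerance = 1e-12)
    expect_equal(mae(7 * est, 7 * ref), 7 * mae(est, ref), tolerance = 1e-12)
  }
  expect_error(mae(1:3, 1:2), "length mismatch")
  expect_error(mre(c(1, 2), c(1, 0)), "> 0")
})

test_that("the error table reports MAE, MRE and max relative error per dimension", {
  man <- data.frame(id = c("a", "b"), body_height_cm = c(130, 128),
                    lumbar_height_cm = c(132, 131), body_length_cm = c(150, 149),
                    chest_girth_cm = c(180, 178))
  aut <- man
  aut$body_height_cm <- aut$body_height_cm + c(1, -2)
  tab <- measurementErrorTable(man, aut)
  expect_equal(tab$body_height_cm,
               c(1.5, 100 * mean(c(1 / 130, 2 / 128)), 100 * 2 / 128),
               tolerance = 1e-12)
  expect_equal(tab$chest_girth_cm, c(0, 0, 0))
  aut2 <- aut; aut2$id <- c("a", "zzz")
  expect_error(measurementErrorTable(man, aut2), "unmatched ids")
})
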