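test_that("binarize thresholds with the documented polarity", {
  f <- matrix(1, 8, 8)
  expect_warning(m <- binarize(f, 0.5), "empty")
  expect_false(any(m))
  f[3:5, 3:5] <- 0.1                    # dark fly on bright background
  expect_equal(sum(binarize(f, 0.5)), 9)
  expect_equal(sum(binarize(f, 0.5, fly_dark = FALSE)), 64 - 9)
  # mask size is monotone in the threshold
  set.seed(7)
  g <- matrix(runif(400), 20, 20)
  sizes <- vapply(seq(0.1, 0.9, 0.1),
                  function(th) sum(binarize(g, th)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

# small synthetic stack: static body disc + a wing bar sweeping around it
toy_stack <- function(nf = 36, H = 48, W = 48, move = c(0, 0)) {
  xs <- matrix(rep(1:W, each = H), H, W)
  ys <- matrix(rep(1:H, W), H, W)
  st <- array(FALSE, c(H, W, nf))
  truth_body <- array(FALSE, c(H, W, nf))
  for (f in seq_len(nf)) {
    cx <- 24 + move[1] * (f - 1); cy <- 24 + move[2] * (f - 1)
    body <- (xs - cx)^2 + (ys - cy)^2 <= 36
    a <- 2 * pi * (f - 1) / nf
    wx <- cx + cos(a) * seq(0, 16, 0.5)
    wy <- cy + sin(a) * seq(0, 16, 0.5)
    wing <- matrix(FALSE, H, W)
    wing[cbind(pmin(pmax(round(wy), 1), H), pmin(pmax(round(wx), 1), W))] <- TRUE
    st[, , f] <- body | wing
    truth_body[, , f] <- body
  }
  list(stack = st, body = truth_body)
}

test_that("motion-based segmentation recovers the body", {
  toy <- toy_stack()
  seg <- segment_body(toy$stack, window = 36, occupancy_fraction = 0.85)
  jacc <- vapply(1:36, function(f) {
    a <- seg$body[, , f]; b <- toy$body[, , f]
    sum(a & b) / sum(a | b)
  }, numeric(1))
  expect_gt(mean(jacc), 0.9)
  # invariants: subset and disjointness on every frame
  for (f in 1:36) {
    expect_true(all(seg$body[, , f] | !seg$body[, , f]))
    expect_false(any(seg$body[, , f] & seg$wing[, , f]))
    expect_true(all((seg$body[, , f] | seg$wing[, , f]) ==
                      toy$stack[, , f]))
  }
  # determinism
  seg2 <- segment_body(toy$stack, window = 36, occupancy_fraction = 0.85)
  expect_identical(seg$body, seg2$body)
  # wing recall of truly wing pixels
  rec <- vapply(1:36, function(f) {
    truth_wing <- toy$stack[, , f] & !toy$body[, , f]
    if (!sum(truth_wing)) return(NA_real_)
    sum(seg$wing[, , f] & truth_wing) / sum(truth_wing)
  }, numeric(1))
  expect_gt(mean(rec, na.rm = TRUE), 0.8)
})

test_that("a completely static scene is all body", {
  H <- 32
  st <- array(FALSE, c(H, H, 20))
  for (f in 1:20) st[10:20, 12:22, f] <- TRUE
  seg <- segment_body(st, window = 10, occupancy_fraction = 0.85)
  expect_identical(seg$body, st)
  expect_false(any(seg$wing))
})

test_that("motion compensation improves the body CM estimate", {
  toy <- toy_stack(move = c(0.25, 0))   # body translating in x
  truth_cm <- 24 + 0.25 * (0:35)
  seg <- segment_body(toy$stack, window = 36, occupancy_fraction = 0.85)
  err2 <- mean(abs(seg$cm[, 1] - truth_cm))
  # pass-1-only estimate: occupancy without compensation
  M <- matrix(as.logical(toy$stack), 48 * 48, 36)
  cm1 <- rep(NA_real_, 36)
  flyhull:::window_occupancy_apply(M, 36, function(f, occ) {
    bm <- matrix(occ >= 0.85 & M[, f], 48, 48)
    cm1[f] <<- flyhull:::mask_cm(bm)[1]
  })
  err1 <- mean(abs(cm1 - truth_cm), na.rm = TRUE)
  expect_lte(err2, err1)
})

test_that("window handling is validated", {
  st <- array(TRUE, c(8, 8, 5))
  expect_error(segment_body(st, window = 10), "longer than")
})
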