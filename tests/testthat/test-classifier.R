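make_records <- function(n_bird, n_drone) {
  c(lapply(seq_len(n_bird), function(i)
      trajectory_record(matrix(rnorm(30), 10), is_drone = FALSE)),
    lapply(seq_len(n_drone), function(i)
      trajectory_record(matrix(rnorm(30), 10), is_drone = TRUE)))
}

test_that("the stratified split is balanced, disjoint and seeded", {
  set.seed(1)
  recs <- make_records(10, 10)
  sp <- split_dataset(recs, 0.8, seed = 4)
  expect_length(sp$train, 16)
  expect_length(sp$test, 4)
  lab <- function(rs) sum(vapply(rs, function(r) r$is_drone, logical(1)))
  expect_equal(lab(sp$train), 8)
  expect_equal(lab(sp$test), 2)
  sp2 <- split_dataset(recs, 0.8, seed = 4)
  expect_identical(sp$train, sp2$train)
  # every record lands in exactly one side
  expect_equal(length(sp$train) + length(sp$test), length(recs))
  expect_error(split_dataset(recs[1:10], 0.8), "both classes")
})

test_that("normalization statistics match hand arithmetic", {
  r1 <- trajectory_record(rbind(c(0, 0, 0), c(2, 4, 6)), FALSE)
  r2 <- trajectory_record(rbind(c(1, 2, 3), c(1, 2, 3)), TRUE)
  st <- compute_stats(list(r1, r2))
  expect_equal(unname(st$mu), c(1, 2, 3))
  # population std of {0,2,1,1}, {0,4,2,2}, {0,6,3,3}
  expect_equal(unname(st$sigma),
               c(sqrt(mean((c(0, 2, 1, 1) - 1)^2)),
                 sqrt(mean((c(0, 4, 2, 2) - 2)^2)),
                 sqrt(mean((c(0, 6, 3, 3) - 3)^2))), tolerance = 1e-12)
  # degenerate feature floored, not zero
  st2 <- compute_stats(list(r2))
  expect_true(all(st2$sigma >= 1e-8))
  expect_error(compute_stats(list()), "non-empty")
})

test_that("normalize / denormalize round trip to 1e-10", {
  set.seed(2)
  x <- matrix(rnorm(60, sd = 30), ncol = 3)
  st <- compute_stats(list(trajectory_record(x, FALSE)))
  xn <- normalize(x, st)
  expect_equal(colMeans(xn), c(0, 0, 0), tolerance = 1e-10)
  expect_lt(max(abs(denormalize(xn, st) - x)), 1e-10)
})

test_that("padding and masking cover short, exact and long sequences", {
  seqs <- list(matrix(1, 3, 3), matrix(2, 5, 3), matrix(3, 8, 3))
  pm <- pad_and_mask(seqs, max_len = 5)
  expect_equal(dim(pm$x), c(3, 5, 3))
  expect_equal(rowSums(pm$mask), c(3, 5, 5))
  # padded frames are zero
  expect_true(all(pm$x[1, 4:5, ] == 0))
  # truncation keeps the first max_len frames
  expect_true(all(pm$x[3, , ] == 3))
  expect_error(pad_and_mask(list()), "empty")
})

test_that("masked BCE matches closed forms and ignores padding bit-exactly", {
  # p = 0.5 everywhere -> loss = log 2
  p <- matrix(0.5, 2, 4); y <- matrix(c(1, 0), 2, 4); m <- matrix(1, 2, 4)
  expect_equal(masked_bce(p, y, m), log(2), tolerance = 1e-12)

  # arbitrary junk on masked-out frames changes nothing, bit for bit
  set.seed(3)
  p <- matrix(runif(8), 2, 4)
  m2 <- m; m2[, 4] <- 0
  base <- masked_bce(p, y, m2)
  p_junk <- p; p_junk[, 4] <- runif(2)
  expect_identical(masked_bce(p_junk, y, m2), base)
  expect_error(masked_bce(p, y, 0 * m), "mask")
})

test_that("sequence probability is the masked per-frame mean", {
  p <- matrix(c(0.2, 0.8, 0.4, 0.6), 2, 2)
  m <- matrix(c(1, 1, 1, 0), 2, 2)
  expect_equal(sequence_probability(p, m), c((0.2 + 0.4) / 2, 0.8))
  expect_equal(sequence_probability(c(0.1, 0.9), c(1, 1)), 0.5)
})

test_that("rank AUC matches hand-computed values", {
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  # ties get midrank credit
  expect_equal(auc_score(c(1, 1), c(0, 1)), 0.5)
  # label-independent scores concentrate near 1/2
  set.seed(4)
  s <- rnorm(2000); l <- rbinom(2000, 1, 0.5)
  expect_equal(auc_score(s, l), 0.5, tolerance = 0.05)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("the forward pass has the right shape, range and determinism", {
  set.seed(5)
  cfg <- tiny_config()
  params <- skyclass:::rnn_init_params("lstm", 3, cfg$hidden)
  x <- array(rnorm(4 * 10 * 3), c(4, 10, 3))
  p1 <- skyclass:::rnn_forward_eval(params, x, "lstm")
  expect_equal(dim(p1), c(4, 10))
  expect_true(all(p1 > 0 & p1 < 1))
  p2 <- skyclass:::rnn_forward_eval(params, x, "lstm")
  expect_identical(p1, p2) # evaluation mode is deterministic

  # a zero head always answers 1/2 regardless of the input
  params$head_W <- 0 * params$head_W
  params$head_b <- 0
  expect_true(all(abs(skyclass:::rnn_forward_eval(params, x, "lstm") -
                        0.5) < 1e-12))

  # GRU path too
  pg <- skyclass:::rnn_init_params("gru", 3, cfg$hidden)
  g1 <- skyclass:::rnn_forward_eval(pg, x, "gru")
  expect_equal(dim(g1), c(4, 10))
  expect_true(all(g1 > 0 & g1 < 1))
})

test_that("classifier_config validates its arguments", {
  expect_error(classifier_config(dropout = 1), "dropout")
  expect_error(classifier_config(layers = 3), "two-layer")
  expect_error(classifier_config(split_fraction = 1), "split_fraction")
  expect_error(classifier_config(cell = "rnn"))
  cfg <- classifier_config()
  expect_equal(cfg$hidden, 64L)
  expect_equal(cfg$max_len, 100L)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_equal(cfg$epochs, 35L)
})
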