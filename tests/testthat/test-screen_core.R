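make_meas <- function(pre, post, plate = "P1", replicate = 1L,
                      role = "sample") {
  n <- length(pre)
  data.frame(plate = plate, well = sprintf("W%02d", seq_len(n)),
             replicate = replicate, phase = rep(c("pre", "post"), each = n),
             fluorescence = c(pre, post), role = role,
             sirna_id = sprintf("si%02d", seq_len(n)))
}

test_that("survival is post over pre, with degenerate wells flagged not NaN", {
  m <- make_meas(pre = c(1000, 2000, 0), post = c(1000, 500, 500))
  s <- suppressMessages(compute_survival(m))
  expect_equal(s$survival[s$well == "W01"], 1.0)
  expect_equal(s$survival[s$well == "W02"], 0.25)
  expect_false(s$valid[s$well == "W03"])
  expect_match(s$reason[s$well == "W03"], "zero")
  expect_true(is.na(s$survival[s$well == "W03"]))

  # a well missing its post-phase reading is reported missing with a reason
  m2 <- make_meas(pre = c(1000, 1000), post = c(900, 900))
  m2 <- m2[-4L, ]
  s2 <- suppressMessages(compute_survival(m2))
  expect_match(s2$reason[s2$well == "W02"], "post-treatment")

  # duplicated (plate, well, replicate, phase) is a hard error
  expect_error(compute_survival(rbind(m, m[1L, ])), "duplicate")
})

test_that("viability filter removes exactly floor(fraction*n) lowest-pre wells", {
  m <- make_meas(pre = 1:10 * 100, post = rep(500, 10))
  s <- compute_survival(m)
  f <- filter_low_viability(s, 0.2)
  expect_equal(nrow(f), 8L)
  expect_setequal(attr(f, "removed")$well, c("W01", "W02"))

  # all-tied pre: exactly one removed, lowest well id
  m2 <- make_meas(pre = rep(100, 5), post = rep(50, 5))
  f2 <- filter_low_viability(compute_survival(m2), 0.2)
  expect_equal(attr(f2, "removed")$well, "W01")

  # count check against a direct sort on lognormal draws
  withr::local_seed(11)
  pre <- rlnorm(100, 9, 0.3)
  m3 <- make_meas(pre = pre, post = pre * 0.5)
  f3 <- filter_low_viability(compute_survival(m3), 0.2)
  expect_equal(nrow(f3), 80L)
  expect_setequal(attr(f3, "removed")$well,
                  sprintf("W%02d", order(pre)[1:20]))

  # controls are never removed
  mc <- rbind(make_meas(pre = 1:5 * 100, post = rep(100, 5)),
              make_meas(pre = c(1, 2), post = c(1, 2), role = "neg_ctrl",
                        plate = "P2"))
  fc <- filter_low_viability(compute_survival(mc), 0.4)
  expect_equal(sum(fc$role == "neg_ctrl"), 2L)
  expect_error(filter_low_viability(s, 1), "fraction")
})

test_that("replicate z uses median and 1.4826*MAD of plate-centred log survival", {
  # plate median of log-survival 1..5 is 3; centred values -2..2;
  # z of the top well = 2 / (1.4826 * 1)
  s <- make_survival(log_survival = 1:5)
  z <- score_replicate(s, 1L)
  expect_equal(max(z$z), 2 / 1.4826, tolerance = 1e-12)
  expect_equal(round(max(z$z), 3), 1.349)

  # identical survival everywhere: MAD 0 -> missing with a warning
  s0 <- make_survival(log_survival = rep(-0.5, 6))
  expect_warning(z0 <- score_replicate(s0, 1L), "deviation is zero")
  expect_true(all(is.na(z0$z)))

  # shift invariance: adding a constant to every log survival
  s1 <- make_survival(log_survival = c(0.1, -0.4, 0.9, -1.2, 0.3))
  s2 <- s1
  s2$survival <- s1$survival * exp(0.73)
  expect_equal(score_replicate(s1, 1L)$z, score_replicate(s2, 1L)$z,
               tolerance = 1e-12)
  expect_error(score_replicate(make_survival(1:2), 1L), "at least 3")
})

test_that("scores are invariant to a per-plate rescaling of fluorescence", {
  toy <- make_toy_screen(n = 12, seed = 5)
  sc1 <- suppressMessages(score_screen(toy$library, toy$measurements))
  m2 <- toy$measurements
  # multiply all post-phase readings on one plate by a positive constant
  sel <- m2$plate == "P1" & m2$phase == "post"
  m2$fluorescence[sel] <- m2$fluorescence[sel] * 4.2
  sc2 <- suppressMessages(score_screen(toy$library, m2))
  expect_equal(sc1$score, sc2$score, tolerance = 1e-12)
  expect_equal(sc1$rank, sc2$rank)
})

test_that("min-of-replicates summary and missing-replicate policy", {
  sc <- data.frame(plate = "P1", well = c("A", "B", "A", "B"),
                   replicate = c(1L, 1L, 2L, 2L), role = "sample",
                   sirna_id = c("s1", "s2", "s1", "s2"),
                   z = c(2, NA, 3, 2.5))
  out <- suppressMessages(summarize_min_replicate(sc))
  expect_equal(out$score[out$sirna_id == "s1"], 2)
  expect_true(is.na(out$score[out$sirna_id == "s2"]))
  expect_true(is.na(out$rank[out$sirna_id == "s2"]))
  expect_equal(out$rank[out$sirna_id == "s1"], 1L)
  # score never exceeds any replicate z
  expect_true(all(out$score <= out$z_rep1, na.rm = TRUE))
  expect_true(all(out$score <= out$z_rep2, na.rm = TRUE))
  # empty input -> empty output
  expect_equal(nrow(summarize_min_replicate(sc[0, ])), 0L)
})

test_that("full pipeline agrees with a brute-force reimplementation", {
  toy <- make_toy_screen(n = 10, n_plates = 2, n_reps = 2, seed = 42)
  got <- suppressMessages(score_screen(toy$library, toy$measurements))
  want <- naive_screen_scores(toy$library, toy$measurements)
  expect_equal(setNames(got$score, got$sirna_id)[names(want)], want,
               tolerance = 1e-12)
})

test_that("Z' matches its definition and rejects degenerate inputs", {
  expect_equal(zprime(c(9, 10, 11), c(-1, 0, 1)), 0.4)
  expect_equal(zprime(c(5, 5), c(1, 1)), 1.0)
  expect_error(zprime(c(1, 2), c(2, 1)), "equal")
  expect_error(zprime(3, c(1, 2)), "two values")
})
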