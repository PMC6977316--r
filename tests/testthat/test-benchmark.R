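# Tanimoto, 1-NN, metric panel, split protocol, Y-randomization.

test_that("tanimoto matches hand counts and handles edge cases", {
  expect_equal(tanimoto("1010", "1010"), 1)
  expect_equal(tanimoto("1100", "0011"), 0)
  expect_equal(tanimoto("1110", "0110"), 2 / 3)
  expect_equal(tanimoto("0000", "0000"), 0) # all-zero convention
  expect_error(tanimoto("10", "100"), class = "ncmfp_length_error")
})

test_that("tanimoto is symmetric, bounded, and 1 on self", {
  withr::with_seed(3, {
    for (k in 1:50) {
      a <- stats::rbinom(32, 1, 0.3)
      b <- stats::rbinom(32, 1, 0.3)
      t1 <- tanimoto(a, b)
      expect_equal(t1, tanimoto(b, a))
      expect_gte(t1, 0); expect_lte(t1, 1)
      if (sum(a) > 0) expect_equal(tanimoto(a, a), 1)
    }
  })
})

test_that("tanimoto_matrix agrees with pairwise tanimoto", {
  withr::with_seed(4, {
    A <- matrix(stats::rbinom(5 * 16, 1, 0.4), nrow = 5)
    B <- matrix(stats::rbinom(3 * 16, 1, 0.4), nrow = 3)
    M <- tanimoto_matrix(A, B)
    for (i in 1:5) for (j in 1:3) {
      expect_equal(M[i, j], tanimoto(A[i, ], B[j, ]))
    }
  })
})

test_that("one_nn_predict returns the most similar label, ties logged", {
  train <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  labs <- c("a", "b")
  expect_equal(one_nn_predict(train, labs, c(1, 1, 0, 0)), "a")
  expect_equal(one_nn_predict(train[1, , drop = FALSE], "a", c(0, 0, 1, 1)), "a")
  # two equidistant neighbours with different labels: first in order wins
  expect_message(
    p <- one_nn_predict(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)), c("x", "y"),
                        c(1, 1, 1, 1)),
    class = "ncmfp_note"
  )
  expect_equal(p, "x")
  expect_error(one_nn_predict(train[0, , drop = FALSE], character(0), c(1, 0, 0, 0)),
               class = "ncmfp_input_error")
})

test_that("confusion_metrics matches worked examples", {
  perfect <- confusion_metrics(list(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(perfect$accuracy, 1); expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)

  inverted <- confusion_metrics(list(TP = 0, FP = 10, TN = 0, FN = 10))
  expect_equal(inverted$accuracy, 0); expect_equal(inverted$mcc, -1)

  m <- confusion_metrics(list(TP = 50, FP = 10, TN = 30, FN = 10))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.8333, tolerance = 1e-4)
  expect_equal(m$f1, 0.8333, tolerance = 1e-4)
  expect_equal(m$mcc, 0.5833, tolerance = 1e-4)

  expect_error(confusion_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               class = "ncmfp_input_error")
})

test_that("confusion_metrics agrees with textbook formulas on random tables", {
  withr::with_seed(99, {
    for (k in 1:1000) {
      cc <- as.list(stats::rpois(4, lambda = sample(1:40, 1)))
      names(cc) <- c("TP", "FP", "TN", "FN")
      if (Reduce(`+`, cc) == 0) cc$TP <- 1L
      got <- confusion_metrics(cc)
      want <- bf_metrics(cc$TP, cc$FP, cc$TN, cc$FN)
      for (nm in names(want)) {
        expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
      }
    }
  })
})

test_that("label_activity applies the strict 10 micromolar threshold", {
  expect_equal(as.character(label_activity(c(5, 10, 15))),
               c("active", "inactive", "inactive"))
  expect_error(label_activity(c(5, NA)), class = "ncmfp_input_error")
  expect_error(label_activity(-1), class = "ncmfp_input_error")
})

make_bits_data <- function(n = 60, seed = 5, p_signal = 0.9) {
  withr::with_seed(seed, {
    label <- rep(c("active", "inactive"), length.out = n)
    bits <- vapply(seq_len(n), function(i) {
      base <- stats::rbinom(16, 1, 0.3)
      base[1] <- ifelse(label[i] == "active",
                        stats::rbinom(1, 1, p_signal),
                        stats::rbinom(1, 1, 1 - p_signal))
      paste(base, collapse = "")
    }, character(1))
    tibble::tibble(id = sprintf("r%03d", seq_len(n)), label = label, bits = bits)
  })
}

test_that("run_split_protocol splits 80/20, is deterministic, order-invariant", {
  d <- make_bits_data(100)
  task <- run_split_protocol(d, split_protocol(seed = 7))
  pr <- tidy(task)
  expect_equal(unique(pr$n_train), 80)
  expect_equal(unique(pr$n_test), 20)
  expect_equal(nrow(pr), 20) # 10 repeats x {cv, external}
  expect_setequal(unique(pr$phase), c("cv", "external"))

  task2 <- run_split_protocol(d, split_protocol(seed = 7))
  expect_equal(glance(task), glance(task2))

  shuffled <- d[withr::with_seed(1, sample(nrow(d))), ]
  task3 <- run_split_protocol(shuffled, split_protocol(seed = 7))
  expect_equal(glance(task), glance(task3))

  one_class <- d; one_class$label <- "active"
  expect_error(run_split_protocol(one_class), class = "ncmfp_input_error")
  expect_error(run_split_protocol(d[1:5, ]), class = "ncmfp_input_error")
})

test_that("Z-scores follow the substitution formula and flag zero spread", {
  expect_equal(ncmfp:::yrand_z(0.9, 0.1, 0.2), 4.0)
  expect_true(is.na(ncmfp:::yrand_z(0.9, 0.1, 0)))
})

test_that("y_randomization separates signal from shuffled labels", {
  d <- make_bits_data(80, seed = 6, p_signal = 0.97)
  yr <- y_randomization(d, split_protocol(seed = 3, repeats = 5), rounds = 15)
  g <- glance(yr)
  expect_gt(g$z_mcc, 3)
  expect_true(g$significant)
  expect_equal(nrow(tidy(yr)), 15)
  expect_gt(stats::sd(tidy(yr)$accuracy), 0) # shuffles genuinely differ

  # with random labels the original model sits inside the null
  d_rand <- d
  d_rand$label <- withr::with_seed(8, sample(d$label))
  yr2 <- y_randomization(d_rand, split_protocol(seed = 3, repeats = 5), rounds = 15)
  expect_lt(abs(glance(yr2)$z_mcc), 3)

  expect_error(y_randomization(d, rounds = 1), class = "ncmfp_input_error")
})
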