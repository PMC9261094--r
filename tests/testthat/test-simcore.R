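test_that("eligible vectors respect stop and vocabulary flags in order", {
  tab <- toy_table()
  t <- annotate_tokens(c("the", "cat", "zyzzyva", "dog"),
                       c("a", "the", "is", "at"), tab, warn_oov = FALSE)
  expect_equal(rownames(eligible_vectors(t, tab)), c("cat", "dog"))
  expect_equal(rownames(eligible_vectors(t, tab, include_stops = TRUE)),
               c("the", "cat", "dog"))
  all_oov <- annotate_tokens(c("qq", "zz"), "the", tab, warn_oov = FALSE)
  expect_equal(nrow(eligible_vectors(all_oov, tab)), 0)
})

test_that("full-frame similarity matches single-pair and identity cases", {
  u <- c(1, 0); v <- c(cos(pi / 3), sin(pi / 3))  # cosine 0.5
  m <- rbind(u, v)
  expect_equal(asw_full(m, "all_pairs"), 0.5)
  expect_equal(asw_full(m, "adjacent"), 0.5)
  same <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_equal(asw_full(same), 1)
  expect_true(is.na(asw_full(m[1, , drop = FALSE])))
  expect_true(is.na(asw_full(m[0, , drop = FALSE])))
})

test_that("full-frame similarity equals the brute-force pair loop", {
  set.seed(7)
  for (i in 1:20) {
    m <- random_unit_matrix(sample(2:50, 1), 8)
    expect_equal(asw_full(m), oracle_asw_full(m), tolerance = 1e-12)
    expect_equal(asw_full(m, "adjacent"), oracle_asw_full(m, "adjacent"),
                 tolerance = 1e-12)
  }
})

test_that("windowed similarity equals the window-enumeration oracle", {
  set.seed(8)
  for (i in 1:15) {
    m <- random_unit_matrix(sample(11:50, 1), 8)
    expect_equal(asw_window(m, 10), oracle_asw_window(m, 10),
                 tolerance = 1e-12)
    expect_equal(asw_window(m, 10, "adjacent"),
                 oracle_asw_window(m, 10, "adjacent"), tolerance = 1e-12)
    w <- sample(3:8, 1)
    expect_equal(asw_window(m, w), oracle_asw_window(m, w),
                 tolerance = 1e-12)
  }
})

test_that("windowed similarity collapses to full-frame when n <= window", {
  set.seed(9)
  m <- random_unit_matrix(10, 6)
  expect_identical(asw_window(m, 10), asw_full(m))
  expect_identical(asw_window(m[1:4, ], 10), asw_full(m[1:4, ]))
  same <- matrix(rep(c(0.3, 0.4), each = 12), 12, 2)
  expect_equal(asw_window(same, 10), 1)
  expect_error(asw_window(m, 1), "window")
})

test_that("full-frame similarity is order-free but windowed is not", {
  set.seed(10)
  m <- random_unit_matrix(30, 6)
  perm <- sample(30)
  expect_equal(asw_full(m[perm, ]), asw_full(m), tolerance = 1e-12)
  # a structured sequence loses its local structure when shuffled
  blocks <- rbind(random_unit_matrix(1, 6)[rep(1, 15), ],
                  random_unit_matrix(1, 6)[rep(1, 15), ])
  jitter <- 0.05 * matrix(rnorm(30 * 6), 30, 6)
  structured <- (blocks + jitter) / sqrt(rowSums((blocks + jitter)^2))
  shuffled <- structured[sample(30), ]
  expect_gt(abs(asw_window(structured, 10) - asw_window(shuffled, 10)),
            1e-6)
})

test_that("similarity metrics are invariant to positive vector rescaling", {
  set.seed(11)
  m <- random_unit_matrix(25, 5)
  scaled <- m * runif(25, 0.1, 10)
  expect_equal(asw_full(scaled), asw_full(m), tolerance = 1e-12)
  expect_equal(asw_window(scaled, 10), asw_window(m, 10), tolerance = 1e-12)
})

test_that("transcript profiles bundle NW and similarity with NA propagation", {
  tab <- toy_table()
  t <- annotate_tokens(c("cat", "cat"), character(0), tab, warn_oov = FALSE,
                       subject_id = "s1", picture_id = "1",
                       timepoint = "baseline")
  p <- profile_transcript(t, tab)
  expect_equal(p$NW, 2)
  expect_equal(p$ASW_F, 1)
  expect_equal(p$ASW_10, 1)
  expect_equal(p$n_eligible, 2)

  empty <- annotate_tokens(character(0), character(0), tab,
                           subject_id = "s1", picture_id = "2",
                           timepoint = "baseline")
  pe <- profile_transcript(empty, tab)
  expect_equal(pe$NW, 0)
  expect_true(is.na(pe$ASW_F) && is.na(pe$ASW_10))
})

test_that("subject aggregation averages defined picture values", {
  base <- data.frame(subject_id = "s1", timepoint = "baseline",
                     NW = c(60, 70, 80), n_eligible = c(30, 35, 40),
                     picture_id = as.character(1:3),
                     ASW_F = c(0.30, 0.35, 0.40),
                     ASW_10 = c(0.4, 0.45, 0.5))
  agg <- aggregate_subject(base)
  expect_equal(agg$ASW_F_mean, 0.35)
  expect_equal(agg$n_pictures, 3)

  base$ASW_F[2] <- NA
  expect_warning(agg2 <- aggregate_subject(base), "undefined")
  expect_equal(agg2$ASW_F_mean, 0.35)
  expect_equal(agg2$n_pictures, 3)

  single <- base[1, ]
  expect_equal(aggregate_subject(single)$ASW_F_mean, base$ASW_F[1])

  base$ASW_F <- NA_real_
  expect_warning(agg3 <- aggregate_subject(base))
  expect_true(is.na(agg3$ASW_F_mean))

  base$subject_id <- c("s1", "s2", "s1")
  expect_error(aggregate_subject(base), "share")
})
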