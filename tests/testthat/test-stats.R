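test_that("quartiles use linear interpolation and match an order-statistic
           oracle", {
  expect_equal(unname(quartiles(1:5)), c(3, 2, 4))
  expect_equal(unname(quartiles(rep(7, 4))), c(7, 7, 7))
  expect_error(quartiles(numeric(0)), "empty")
  oracle <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  set.seed(12)
  for (i in 1:100) {
    x <- rnorm(sample(3:40, 1))
    q <- quartiles(x)
    expect_equal(unname(q), c(oracle(x, 0.5), oracle(x, 0.25),
                              oracle(x, 0.75)), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U: exact example, degenerate case and exact vs
           approximate agreement", {
  t1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(t1$statistic), 0)
  expect_equal(t1$p_value, 0.1)   # 2/20 orderings are as extreme
  expect_match(t1$method, "exact")
  expect_warning(t2 <- mann_whitney_u(rep(1, 4), rep(1, 4)),
                 "degenerate|identical")
  expect_equal(t2$p_value, 1)
  set.seed(13)
  for (i in 1:50) {
    a <- rnorm(8); b <- rnorm(8)
    pe <- mann_whitney_u(a, b, mode = "exact")$p_value
    pa <- mann_whitney_u(a, b, mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("the exact Mann-Whitney p matches full enumeration over all
           group assignments", {
  enum_p <- function(a, b) {
    n1 <- length(a); pooled <- c(a, b)
    u_of <- function(idx) {
      x <- pooled[idx]; y <- pooled[-idx]
      sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    }
    obs <- u_of(seq_len(n1))
    mu <- n1 * length(b) / 2
    us <- combn(length(pooled), n1, u_of)
    mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
  }
  set.seed(14)
  for (i in 1:15) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney_u(a, b, mode = "exact")$p_value,
                 enum_p(a, b), tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis reduces to the squared standardized rank-sum at
           k = 2 and is calibrated under the null", {
  set.seed(15)
  x <- rnorm(40); y <- rnorm(35)
  kw <- kruskal_wallis(list(x, y))
  z <- steel_dwass(list(x, y))$z
  expect_equal(unname(kw$statistic), z^2, tolerance = 1e-6)
  same <- list(c(1, 2, 3), c(1, 2, 3))
  kw0 <- kruskal_wallis(same)
  expect_equal(unname(kw0$statistic), 0, tolerance = 1e-12)
  expect_equal(kw0$p_value, 1)
})

test_that("Mann-Whitney type-I error is near nominal (two groups of 30)", {
  set.seed(16)
  hits <- 0L
  n_rep <- 10000L
  for (i in seq_len(n_rep)) {
    if (mann_whitney_u(rnorm(30), rnorm(30),
                       mode = "approx")$p_value < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_lt(abs(hits / n_rep - 0.05), 0.01)
})

test_that("Steel-Dwass reduces to Mann-Whitney at k = 2, saturates on
           identical groups, and dominates the unadjusted pairwise p", {
  set.seed(17)
  x <- rnorm(25); y <- rnorm(30)
  sd2 <- steel_dwass(list(x, y))
  mw <- mann_whitney_u(x, y, mode = "approx", continuity = FALSE)
  expect_lt(abs(sd2$p_value - mw$p_value), 1e-6)
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(all(steel_dwass(g)$p_value >= 0.999))
  expect_error(steel_dwass(list(rnorm(5), rnorm(1))), "n >= 2")
  for (i in 1:100) {
    gs <- lapply(1:3, function(k) rnorm(sample(5:15, 1)))
    tab <- steel_dwass(gs)
    pair <- list(c(1, 2), c(1, 3), c(2, 3))
    for (r in 1:3) {
      mwp <- mann_whitney_u(gs[[pair[[r]][1]]], gs[[pair[[r]][2]]],
                            mode = "approx",
                            continuity = FALSE)$p_value
      expect_gte(tab$p_value[r] + 1e-12, mwp)
    }
  }
})

test_that("the grouped report assembles quartiles, tests and schema for a
           multi-sample cohort", {
  set.seed(18)
  n_samp <- 6
  units <- do.call(rbind, lapply(seq_len(n_samp), function(s) {
    n <- 40
    pos <- runif(n) < c(0.3, 0.5, 0.7, 0.3, 0.5, 0.7)[s]
    tibble::tibble(sample_id = paste0("S", s), unit_id = seq_len(n),
                   abeta_positive = pos,
                   d0_diameter_um = rlnorm(n, log(ifelse(pos, 36, 26)),
                                           0.3),
                   density_per_um = rgamma(n, 4, 200),
                   sma_onset_label = ifelse(pos & runif(n) < 0.5, "LMA",
                                            NA))
  }))
  segs <- do.call(rbind, lapply(seq_len(nrow(units)), function(i)
    tibble::tibble(sample_id = units$sample_id[i],
                   unit_id = units$unit_id[i],
                   label = c("LMA", "D0"),
                   abeta_positive = units$abeta_positive[i])))
  meta <- tibble::tibble(sample_id = paste0("S", 1:n_samp),
                         region = rep(c("frontal", "occipital"), 3),
                         caa_type = rep(c(1, 2), each = 3))
  rep <- build_report(units, segs, meta)
  expect_s3_class(rep, "caa_report")
  expect_equal(nrow(rep$sample_loads), n_samp)
  expect_true(all(rep$sample_loads$load_class %in%
                    c("low", "moderate", "high")))
  expect_s3_class(rep$diameter$overall$test, "caa_test")
  expect_true(!is.null(rep$density_by_load$kruskal))
  expect_equal(nrow(rep$density_by_load$steel_dwass), 3)
  d <- withr::local_tempdir()
  write_report(rep, d)
  expect_true(file.exists(file.path(d, "report.json")))
  expect_true(file.exists(file.path(d, "sample_loads.csv")))
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_identical(js$schema_version, "1.0")
})

test_that("a single-sample report has quartiles but no group tests", {
  units <- tibble::tibble(sample_id = "S1", unit_id = 1:20,
                          abeta_positive = rep(c(TRUE, FALSE), 10),
                          d0_diameter_um = seq(20, 58, by = 2))
  segs <- tibble::tibble(sample_id = "S1", unit_id = 1:20, label = "D0",
                         abeta_positive = units$abeta_positive)
  meta <- tibble::tibble(sample_id = "S1", region = "frontal",
                         caa_type = 1)
  rep <- build_report(units, segs, meta)
  expect_null(rep$density_by_load)
  expect_null(rep$density_by_region)
  expect_true(!is.null(rep$diameter$overall))
})
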