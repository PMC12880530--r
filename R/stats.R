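#' Quartile summary
#'
#' Median and 25th/75th percentiles with linear interpolation between
#' order statistics, the convention used throughout the report tables.
#'
#' @param values non-empty numeric vector.
#' @return named numeric: `median`, `q25`, `q75`.
#' @export
quartiles <- function(values) {
  if (!length(values)) stop("quartiles of an empty vector are undefined")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

caa_test <- function(statistic, p, method, sizes, ties, extra = list()) {
  structure(c(list(statistic = unname(statistic), p_value = unname(p),
                   method = method, group_sizes = sizes,
                   tie_corrected = ties), extra),
            class = "caa_test")
}

#' @export
print.caa_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n", x$method,
              x$statistic, x$p_value,
              paste(x$group_sizes, collapse = ", "),
              if (x$tie_corrected) ", tie-corrected" else ""))
  invisible(x)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration when both groups have at most 8 observations and
#' there are no ties; otherwise the tie-corrected normal approximation
#' (with continuity correction by default). When every value is identical
#' across both groups the test is degenerate and returns p = 1 with a
#' warning.
#'
#' @param a,b non-empty numeric vectors.
#' @param mode `"auto"` (default), `"exact"` or `"approx"`. An exact
#'   request with ties falls back to the approximation with a warning.
#' @param continuity apply the continuity correction in the approximate
#'   mode (default `TRUE`; disable to match the Steel-Dwass k = 2
#'   reduction exactly).
#' @return a `caa_test` with the U statistic of the first group.
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "approx"),
                           continuity = TRUE) {
  mode <- match.arg(mode)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(unique(c(a, b))) == 1) {
    warning("all values identical across groups; test is degenerate")
    return(caa_test(length(a) * length(b) / 2, 1,
                    "Mann-Whitney U (degenerate)",
                    c(length(a), length(b)), TRUE))
  }
  exact <- switch(mode,
    auto = length(a) <= 8 && length(b) <= 8 && !ties,
    exact = TRUE,
    approx = FALSE)
  if (exact && ties) {
    warning("exact enumeration not available with ties; using the ",
            "tie-corrected normal approximation")
    exact <- FALSE
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = continuity))
  caa_test(wt$statistic, wt$p.value,
           if (exact) "Mann-Whitney U (exact)"
           else "Mann-Whitney U (normal approximation)",
           c(length(a), length(b)), ties && !exact)
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups list of non-empty numeric vectors.
#' @return a `caa_test`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  kt <- stats::kruskal.test(groups)
  caa_test(kt$statistic, kt$p.value, "Kruskal-Wallis",
           lengths(groups), anyDuplicated(unlist(groups)) > 0,
           list(df = unname(kt$parameter)))
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For each unordered pair of groups, only that pair's pooled data are
#' mid-ranked and the tie-corrected standardized Mann-Whitney statistic z
#' is computed; the familywise-adjusted p-value is
#' P(Q[k, Inf] >= |z| sqrt(2)) from the studentized-range distribution
#' with k groups and infinite degrees of freedom (the asymptotic form
#' used by standard statistical packages). At k = 2 this reduces to the
#' two-sided normal-approximation Mann-Whitney test without continuity
#' correction.
#'
#' @param groups list of k >= 2 numeric vectors, each with n >= 2.
#' @param names optional group names (defaults to list names or G1..Gk).
#' @return tibble with one row per pair: `group_a`, `group_b`, `z`,
#'   `p_value`.
#' @export
steel_dwass <- function(groups, names = NULL) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2")
  if (is.null(names)) {
    names <- if (!is.null(base::names(groups))) base::names(groups)
             else paste0("G", seq_len(k))
  }
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      x <- groups[[i]]; y <- groups[[j]]
      n1 <- length(x); n2 <- length(y); n <- n1 + n2
      r <- rank(c(x, y))
      r1 <- sum(r[seq_len(n1)])
      e <- n1 * (n + 1) / 2
      v <- n1 * n2 / (n * (n - 1)) * sum((r - (n + 1) / 2)^2)
      z <- if (v > 0) (r1 - e) / sqrt(v) else 0
      p <- stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf,
                         lower.tail = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group_a = names[i], group_b = names[j], z = z, p_value = p)
    }
  }
  do.call(rbind, rows)
}

#' Assemble the grouped report of a synthetic cohort
#'
#' Assembles the standard grouped summary: per-sample vascular load and class;
#' D0 diameter comparisons between amyloid-positive and negative units
#' (overall and within region / load class / CAA type strata, Mann-
#' Whitney); perivascular density comparisons (positive vs negative
#' overall, frontal vs occipital, load classes via Kruskal-Wallis +
#' Steel-Dwass, CAA types); pooled per-segment load rates; and per-sample
#' most-superficial-SMA-loss distributions.
#'
#' @param unit_table tibble with one row per unit: `sample_id`,
#'   `unit_id`, `abeta_positive`, and optionally `d0_diameter_um`,
#'   `density_per_um`, `sma_onset_label`, plus segment-status rows are
#'   taken separately.
#' @param segment_status tibble of segment statuses (`sample_id`,
#'   `unit_id`, `label`, `abeta_positive`).
#' @param sample_meta tibble: `sample_id`, `region`
#'   (`"frontal"`/`"occipital"`), `caa_type` (`1`/`2`).
#' @return a nested list (class `caa_report`) of quartile tables and
#'   `caa_test` results; see [write_report()].
#' @export
build_report <- function(unit_table, segment_status, sample_meta) {
  ut <- merge(unit_table, sample_meta, by = "sample_id")
  rep <- list(schema_version = "1.0")

  loads <- lapply(split(ut, ut$sample_id), function(d) {
    frac <- mean(d$abeta_positive)
    tibble::tibble(sample_id = d$sample_id[1], n_units = nrow(d),
                   n_positive = sum(d$abeta_positive),
                   load_fraction = frac, load_class = load_class(frac))
  })
  rep$sample_loads <- do.call(rbind, loads)
  ut <- merge(ut, rep$sample_loads[, c("sample_id", "load_class")],
              by = "sample_id")

  two_group <- function(d, value) {
    d <- d[is.finite(d[[value]]), ]
    pos <- d[[value]][d$abeta_positive]
    neg <- d[[value]][!d$abeta_positive]
    if (length(pos) < 2 || length(neg) < 2) return(NULL)
    list(quartiles = list(positive = quartiles(pos),
                          negative = quartiles(neg)),
         test = mann_whitney_u(pos, neg, mode = "approx"))
  }
  strata <- function(value) {
    out <- list(overall = two_group(ut, value))
    for (split_var in c("region", "load_class", "caa_type")) {
      for (lev in unique(ut[[split_var]])) {
        out[[paste0(split_var, ":", lev)]] <-
          two_group(ut[ut[[split_var]] == lev, ], value)
      }
    }
    out
  }
  if ("d0_diameter_um" %in% names(ut)) {
    rep$diameter <- strata("d0_diameter_um")
  }
  if ("density_per_um" %in% names(ut)) {
    rep$density <- strata("density_per_um")
    dv <- ut[is.finite(ut$density_per_um), ]
    reg <- split(dv$density_per_um, dv$region)
    if (length(reg) == 2 && all(lengths(reg) >= 2)) {
      rep$density_by_region <- list(
        quartiles = lapply(reg, quartiles),
        test = mann_whitney_u(reg[[1]], reg[[2]], mode = "approx"))
    }
    lg <- split(dv$density_per_um, dv$load_class)
    lg <- lg[lengths(lg) >= 2]
    if (length(lg) >= 3) {
      rep$density_by_load <- list(
        quartiles = lapply(lg, quartiles),
        kruskal = kruskal_wallis(lg),
        steel_dwass = steel_dwass(lg))
    }
  }
  pos_st <- merge(segment_status, sample_meta, by = "sample_id")
  rep$segment_rates <- vascular_load(
    pos_st[, c("unit_id", "label", "abeta_positive")])$per_segment_rates
  if ("sma_onset_label" %in% names(ut)) {
    tab <- table(ut$sample_id[!is.na(ut$sma_onset_label)],
                 ut$sma_onset_label[!is.na(ut$sma_onset_label)])
    rep$sma_onset <- as.data.frame.matrix(tab)
  }
  structure(rep, class = "caa_report")
}

#' Write a report to JSON and CSV
#'
#' @param report a `caa_report` from [build_report()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$sample_loads, file.path(dir, "sample_loads.csv"),
                   row.names = FALSE)
  utils::write.csv(report$segment_rates,
                   file.path(dir, "segment_rates.csv"), row.names = FALSE)
  simplify <- function(x) {
    if (inherits(x, "caa_test")) {
      unclass(x)
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, simplify)
    } else {
      x
    }
  }
  jsonlite::write_json(simplify(unclass(report)),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
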