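# Evaluation surfaces: classical item statistics by key location, exponent
# summaries by scheduled option count, DIC model comparison, latent-metric
# spread contrasts, and parameter-recovery reports.

#' Classical item statistics by scheduled option count
#'
#' For each (item, k) cell: the classical p-value (proportion correct) and
#' the item-total correlation, the Pearson correlation between the cell's
#' scores and the contributing examinees' total test scores. Totals are each
#' examinee's own-form total including the item itself (the uncorrected
#' index); set `corrected = TRUE` for the item-rest variant that subtracts
#' the item's score from the total. Cells whose scores or totals have zero
#' variance get an undefined (NA) correlation, are excluded from group
#' means, and trigger a warning.
#'
#' @param data Long-format response table with columns `examinee_id`,
#'   `item_id`, `n_keys`, `k_scheduled`, `score`.
#' @param corrected Use item-rest totals instead of raw totals.
#' @return A list of class `classical_stats`: `by_cell` (per item-by-k) and
#'   `by_group` (means over cells grouped by `n_keys` and k).
#' @export
classical_item_stats <- function(data, corrected = FALSE) {
  if (nrow(data) == 0L) stop("data must be nonempty", call. = FALSE)
  total <- tapply(data$score, data$examinee_id, sum)
  tot <- as.numeric(total[as.character(data$examinee_id)])
  if (corrected) tot <- tot - data$score
  key <- cell_key(data$item_id, data$k_scheduled)
  cells <- !duplicated(key)
  cell_ids <- key[cells]
  p <- as.numeric(tapply(data$score, key, mean)[cell_ids])
  r <- vapply(cell_ids, function(ck) {
    sel <- key == ck
    s <- data$score[sel]
    if (length(s) < 2L || stats::sd(s) == 0 || stats::sd(tot[sel]) == 0) {
      return(NA_real_)
    }
    stats::cor(s, tot[sel])
  }, 1)
  by_cell <- data.frame(item_id = data$item_id[cells],
                        n_keys = data$n_keys[cells],
                        k = data$k_scheduled[cells],
                        n = as.integer(table(key)[cell_ids]),
                        p_value = p, item_total_r = unname(r),
                        stringsAsFactors = FALSE)
  by_cell <- by_cell[order(by_cell$item_id, by_cell$k), ]
  rownames(by_cell) <- NULL
  if (anyNA(by_cell$item_total_r)) {
    warning(sum(is.na(by_cell$item_total_r)),
            " cell(s) with undefined item-total correlation excluded from ",
            "group means", call. = FALSE)
  }
  grp <- split(by_cell, list(by_cell$n_keys, by_cell$k), drop = TRUE)
  by_group <- do.call(rbind, lapply(grp, function(g) {
    data.frame(n_keys = g$n_keys[1L], k = g$k[1L], n_items = nrow(g),
               mean_p = mean(g$p_value),
               mean_item_total_r = mean(g$item_total_r, na.rm = TRUE))
  }))
  by_group <- by_group[order(by_group$n_keys, by_group$k), ]
  rownames(by_group) <- NULL
  structure(list(by_cell = by_cell, by_group = by_group),
            class = "classical_stats")
}

#' Summarize LPE exponents by key count and scheduled option count
#'
#' Mean and SD of the `xi` parameters of a `model4` parameter set, grouped
#' by the item's key count and the scheduled option count k (the layout in
#' which exponent growth with k is read off).
#'
#' @param pset A `model4` [parameter_set()] (e.g., posterior means).
#' @param designs The [item_designs()] table for the items in `pset`.
#' @return Data frame with `n_keys`, `k`, `n_items`, `mean_xi`, `sd_xi`.
#' @export
xi_summary <- function(pset, designs) {
  stopifnot(inherits(pset, "parameter_set"))
  if (pset$model != "model4") {
    stop("xi_summary requires a model4 parameter set", call. = FALSE)
  }
  keys <- names(pset$xi)
  split_at <- regexpr(":[^:]*$", keys)
  item <- substr(keys, 1L, split_at - 1L)
  k <- as.integer(substring(keys, split_at + 1L))
  nk <- designs$n_keys[match(item, designs$item_id)]
  if (anyNA(nk)) stop("xi cells reference unknown items", call. = FALSE)
  df <- data.frame(n_keys = nk, k = k, xi = unname(pset$xi))
  grp <- split(df, list(df$n_keys, df$k), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(n_keys = g$n_keys[1L], k = g$k[1L], n_items = nrow(g),
               mean_xi = mean(g$xi),
               sd_xi = if (nrow(g) > 1L) stats::sd(g$xi) else 0)
  }))
  out <- out[order(out$n_keys, out$k), ]
  rownames(out) <- NULL
  out
}

#' Rank fitted models by DIC
#'
#' @param fits Named list mapping model id to a `dic_result` (or a list of
#'   `(model_id, dic_result)` pairs).
#' @return Data frame sorted ascending by DIC with the winner flagged; exact
#'   ties are broken by model order and flagged in the `tie` column.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fitted models", call. = FALSE)
  ids <- names(fits)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("fits must be a named list of dic_result objects", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate model ids", call. = FALSE)
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    d <- fits[[i]]
    data.frame(model = ids[i], d_bar = d$d_bar, d_hat = d$d_hat, p_d = d$p_d,
               dic = d$dic, stringsAsFactors = FALSE)
  }))
  ord <- order(tab$dic, seq_len(nrow(tab)))  # stable: ties keep input order
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  tab$winner <- tab$rank == 1L
  tab$tie <- duplicated(tab$dic) | duplicated(tab$dic, fromLast = TRUE)
  rownames(tab) <- NULL
  tab
}

#' Latent-metric spread comparison between two calibrations
#'
#' Contrasts the ability estimates that two models assign to the same
#' examinees. Although both calibrations fix the latent metric through the
#' same N(0, 1) ability prior, a symmetric model fit to positively
#' asymmetric items compresses the upper end of the scale; the
#' `upper_decile_sd_ratio` (model a over model b, computed within the top
#' decile) quantifies that shrinkage. Deciles are defined by the reference
#' model's estimates and applied to both models so the comparison is paired.
#'
#' @param theta_a,theta_b Named vectors of ability estimates over the same
#'   examinee ids.
#' @param reference Which model's estimates define the decile partition.
#' @return A list of class `spread_report`: overall SDs and their ratio,
#'   per-decile SDs, the upper-decile SD ratio and ranges, and paired
#'   quantile differences (a minus b at the deciles).
#' @export
metric_spread <- function(theta_a, theta_b, reference = c("b", "a")) {
  reference <- match.arg(reference)
  if (is.null(names(theta_a)) || is.null(names(theta_b)) ||
      !setequal(names(theta_a), names(theta_b)) ||
      length(theta_a) != length(theta_b)) {
    stop("theta_a and theta_b must be named over the same examinee ids",
         call. = FALSE)
  }
  theta_b <- theta_b[names(theta_a)]
  ref <- if (reference == "b") theta_b else theta_a
  dec <- ceiling(rank(ref, ties.method = "first") * 10 / length(ref))
  sd_a <- tapply(theta_a, dec, stats::sd)
  sd_b <- tapply(theta_b, dec, stats::sd)
  probs <- seq(0.1, 0.9, by = 0.1)
  structure(list(
    overall_sd_a = stats::sd(theta_a), overall_sd_b = stats::sd(theta_b),
    overall_sd_ratio = stats::sd(theta_a) / stats::sd(theta_b),
    decile_sd_a = sd_a, decile_sd_b = sd_b,
    decile_sd_ratio = sd_a / sd_b,
    upper_decile_sd_ratio = unname(sd_a[["10"]] / sd_b[["10"]]),
    upper_decile_range_a = diff(range(theta_a[dec == 10L])),
    upper_decile_range_b = diff(range(theta_b[dec == 10L])),
    quantile_diff = stats::quantile(theta_a, probs) -
      stats::quantile(theta_b, probs)),
    class = "spread_report")
}

#' @export
print.spread_report <- function(x, ...) {
  cat(sprintf("overall SD ratio (a/b): %.3f\n", x$overall_sd_ratio))
  cat(sprintf("upper-decile SD ratio (a/b): %.3f\n", x$upper_decile_sd_ratio))
  invisible(x)
}

#' Histogram plot data for contrasting two ability metrics
#'
#' Bins two calibrations' ability estimates on one shared set of bin edges
#' (so the histograms are directly overlayable) and returns the counts as a
#' plain data frame for external plotting.
#'
#' @inheritParams metric_spread
#' @param bin_width Bin width on the theta scale.
#' @return Data frame with `lower`, `upper`, `mid`, `count_a`, `count_b`.
#' @export
theta_histogram_data <- function(theta_a, theta_b, bin_width = 0.25) {
  if (!setequal(names(theta_a), names(theta_b))) {
    stop("theta_a and theta_b must cover the same examinee ids",
         call. = FALSE)
  }
  lo <- floor(min(theta_a, theta_b) / bin_width) * bin_width
  hi <- ceiling(max(theta_a, theta_b) / bin_width) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  bin_of <- function(x) findInterval(x, breaks, rightmost.closed = TRUE,
                                     all.inside = TRUE)
  ca <- tabulate(bin_of(theta_a), nbins = length(breaks) - 1L)
  cb <- tabulate(bin_of(theta_b), nbins = length(breaks) - 1L)
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1L],
             mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
             count_a = ca, count_b = cb)
}

#' Parameter-recovery report
#'
#' Compares an estimated parameter set to the generating truth, per block:
#' mean error (bias), root-mean-square error, and Pearson correlation.
#' Blocks are matched by parameter names; a layout mismatch is an error.
#'
#' @param truth,estimate [parameter_set()] objects with identical layouts.
#' @return Data frame with one row per block (`theta`, `a`, `b`, `xi`, `c`).
#' @export
recovery_report <- function(truth, estimate) {
  stopifnot(inherits(truth, "parameter_set"),
            inherits(estimate, "parameter_set"))
  if (truth$model != estimate$model) {
    stop("parameter sets come from different models", call. = FALSE)
  }
  out <- list()
  for (bn in c("theta", "a", "b", "xi", "c")) {
    tv <- truth[[bn]]; ev <- estimate[[bn]]
    if (is.null(tv) && is.null(ev)) next
    if (length(tv) == 0L && length(ev) == 0L) next
    if (is.null(tv) || is.null(ev) || !setequal(names(tv), names(ev))) {
      stop("layout mismatch in block '", bn, "'", call. = FALSE)
    }
    ev <- ev[names(tv)]
    err <- ev - tv
    out[[bn]] <- data.frame(
      block = bn, n = length(tv), bias = mean(err),
      rmse = sqrt(mean(err^2)),
      cor = if (length(tv) > 1L && stats::sd(tv) > 0 && stats::sd(ev) > 0) {
        stats::cor(tv, ev)
      } else NA_real_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
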