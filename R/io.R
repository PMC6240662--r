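# Readers and writers for the pipeline's file formats: long-format response
# CSV, item-bank JSON, and fit result sets (posterior-summary CSV, DIC JSON,
# R-hat CSV). One dialect throughout: comma-separated, UTF-8, mandatory
# header, no index column.

RESPONSE_COLS <- c("examinee_id", "form_id", "item_id", "n_keys",
                   "k_scheduled", "score")

# Write a data frame with numeric columns at full double precision so that
# a read-back reproduces the values exactly.
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a long-format DOMC response table
#'
#' Validates the header, score binarity and the admissibility of every
#' `k_scheduled` (within `[n_keys, n_options]`, where `n_options` is 5 for
#' triple-keyed items and 4 otherwise); errors cite the offending data row.
#' Item designs are inferred from the key counts.
#'
#' @param path CSV file with columns `examinee_id`, `form_id`, `item_id`,
#'   `n_keys`, `k_scheduled`, `score`.
#' @return A list with `responses` (validated data frame) and `designs`
#'   (an [item_designs()] table).
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RESPONSE_COLS, names(df))
  if (length(missing_cols)) {
    stop("response file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("response file has a header but no records: ", path,
            call. = FALSE)
    designs <- item_designs(character(), integer())
    return(list(responses = df, designs = designs))
  }
  df$examinee_id <- as.character(df$examinee_id)
  df$item_id <- as.character(df$item_id)
  bad <- which(!(df$score %in% c(0L, 1L)))
  if (length(bad)) {
    stop("non-binary score at row ", bad[1L], " (score=", df$score[bad[1L]],
         ")", call. = FALSE)
  }
  n_opt <- ifelse(df$n_keys == 3L, 5L, 4L)
  bad <- which(df$k_scheduled < df$n_keys | df$k_scheduled > n_opt |
                 df$n_keys < 1L | df$n_keys > 3L)
  if (length(bad)) {
    stop("inadmissible k_scheduled/n_keys at row ", bad[1L], " (n_keys=",
         df$n_keys[bad[1L]], ", k=", df$k_scheduled[bad[1L]], ")",
         call. = FALSE)
  }
  per_item <- df[!duplicated(df$item_id), c("item_id", "n_keys")]
  inconsistent <- tapply(df$n_keys, df$item_id, function(v)
    length(unique(v)) > 1L)
  if (any(inconsistent)) {
    stop("item(s) with inconsistent n_keys across rows: ",
         paste(utils::head(names(inconsistent)[inconsistent], 5L),
               collapse = ", "), call. = FALSE)
  }
  designs <- item_designs(per_item$item_id, per_item$n_keys)
  list(responses = df, designs = designs)
}

#' Write a response table (or simulation output) to CSV
#'
#' @param x A response data frame or a `domc_sim` result.
#' @param path Output CSV path.
#' @export
write_responses <- function(x, path) {
  df <- if (inherits(x, "domc_sim")) x$responses else x
  utils::write.csv(df[, intersect(c(RESPONSE_COLS, "extra_shown"),
                                  names(df))],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an item bank (design plus true parameters) to JSON
#'
#' @param bank A [domc_bank()].
#' @param path Output JSON path.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "domc_bank"))
  tp <- bank$true_params
  payload <- list(
    designs = bank$designs, forms = bank$forms,
    true_params = if (is.null(tp)) NULL else {
      pl <- list(model = tp$model)
      for (bn in c("a", "b", "xi", "c", "theta")) {
        if (!is.null(tp[[bn]]) && length(tp[[bn]])) {
          pl[[bn]] <- as.list(tp[[bn]])
        }
      }
      pl
    })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an item bank written by [write_item_bank()]
#'
#' @param path JSON path.
#' @return A [domc_bank()].
#' @export
read_item_bank <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- payload$designs
  designs <- item_designs(
    vapply(d, function(r) as.character(r$item_id), ""),
    vapply(d, function(r) as.integer(r$n_keys), 1L),
    vapply(d, function(r) as.integer(r$n_options), 1L))
  forms <- lapply(payload$forms, function(f) unlist(f, use.names = FALSE))
  tp <- payload$true_params
  true_params <- if (is.null(tp)) NULL else {
    grab <- function(bn) {
      if (is.null(tp[[bn]])) NULL else unlist(tp[[bn]])
    }
    parameter_set(tp$model, a = grab("a"), b = grab("b"), xi = grab("xi"),
                  c = grab("c"),
                  theta = if (is.null(tp$theta)) numeric() else
                    unlist(tp$theta))
  }
  domc_bank(designs, forms, true_params)
}

# Decompose parameter names into (item_id, k) where they follow the
# "item:k" cell convention; item-level and examinee-level names pass
# through with k = NA.
split_param_names <- function(nms, block) {
  if (block == "theta") {
    return(data.frame(item_id = NA_character_, k = NA_integer_,
                      parameter = nms, stringsAsFactors = FALSE))
  }
  has_cell <- grepl(":", nms, fixed = TRUE)
  pos <- regexpr(":[^:]*$", nms)
  data.frame(
    item_id = ifelse(has_cell, substr(nms, 1L, pos - 1L), nms),
    k = ifelse(has_cell, suppressWarnings(as.integer(substring(nms, pos + 1L))),
               NA_integer_),
    parameter = nms, stringsAsFactors = FALSE)
}

#' Write the file set of a completed fit
#'
#' Writes three files into `out_dir`:
#' \describe{
#'   \item{posterior_summary.csv}{block, parameter, item_id, k, mean, sd,
#'     r_hat (NA when the fit has one chain) -- full double precision.}
#'   \item{dic.json}{DIC components plus run metadata (model, iterations,
#'     burn-in, chains, seed).}
#'   \item{rhat.csv}{per-parameter PSRF and pass flag (threshold 1.1).}
#' }
#'
#' @param fit A [fit_domc()] result.
#' @param out_dir Output directory (created if needed).
#' @param burn_in Burn-in override for the summaries.
#' @return Invisibly, the paths written.
#' @export
write_fit_results <- function(fit, out_dir, burn_in = NULL) {
  stopifnot(inherits(fit, "domc_fit"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (is.null(burn_in)) burn_in <- fit$burn_in
  pm <- posterior_summaries(fit, burn_in)
  sds <- attr(pm, "sd")
  diag_df <- if (length(fit$chains) >= 2L) {
    convergence_diagnostics(fit, burn_in)
  } else NULL
  rows <- list()
  block_map <- c(theta = "theta", a = "a", b = "b", xi = "xi", c = "c")
  for (bn in names(block_map)) {
    v <- pm[[bn]]
    if (is.null(v) || !length(v)) next
    sdv <- sds[[bn]]
    info <- split_param_names(names(v), bn)
    rh <- if (is.null(diag_df)) NA_real_ else {
      db <- diag_df[diag_df$block == bn, ]
      db$r_hat[match(names(v), db$parameter)]
    }
    rows[[bn]] <- data.frame(block = bn, parameter = info$parameter,
                             item_id = info$item_id, k = info$k,
                             mean = unname(v),
                             sd = unname(sdv[names(v)]), r_hat = rh,
                             stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  p1 <- file.path(out_dir, "posterior_summary.csv")
  write_csv_full(summary_df, p1)
  d <- dic(fit, burn_in)
  p2 <- file.path(out_dir, "dic.json")
  jsonlite::write_json(
    list(model = fit$model, d_bar = d$d_bar, d_hat = d$d_hat, p_d = d$p_d,
         dic = d$dic, n_iter = fit$n_iter, burn_in = burn_in,
         n_chains = length(fit$chains), seed = fit$seed),
    p2, auto_unbox = TRUE, digits = NA)
  p3 <- file.path(out_dir, "rhat.csv")
  if (is.null(diag_df)) {
    diag_df <- data.frame(block = character(), parameter = character(),
                          r_hat = numeric(), pass = logical())
  }
  write_csv_full(diag_df, p3)
  invisible(c(summary = p1, dic = p2, rhat = p3))
}

#' Read back a fit file set written by [write_fit_results()]
#'
#' @param out_dir Directory holding `posterior_summary.csv`, `dic.json`,
#'   `rhat.csv`.
#' @return A list with `summary` (data frame), `dic` (a `dic_result`),
#'   `meta` (run metadata), and `rhat` (data frame).
#' @export
read_fit_results <- function(out_dir) {
  summary_df <- utils::read.csv(file.path(out_dir, "posterior_summary.csv"),
                                stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(out_dir, "dic.json"),
                              simplifyVector = TRUE)
  rhat <- utils::read.csv(file.path(out_dir, "rhat.csv"),
                          stringsAsFactors = FALSE)
  list(summary = summary_df,
       dic = dic_result(d_bar = meta$d_bar, d_hat = meta$d_hat),
       meta = meta, rhat = rhat)
}
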