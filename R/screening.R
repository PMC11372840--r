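#' Deviation statistics of predicted vs experimental solubility
#'
#' Matches predictions to an experimental table on the `(api, polymer, T_K)`
#' key and computes, per system and in aggregate, the average absolute
#' deviation (AAD), average deviation (AD) and average absolute relative
#' deviation (AARD) of the API weight fraction, all in percent. The sign
#' convention is \eqn{\Delta w = w^{calc} - w^{exp}}, so a positive AD means
#' the model overestimates solubility. AARD is flagged undefined whenever an
#' experimental weight fraction is zero.
#'
#' @param exp_table data.frame with columns `api`, `polymer`, `T_K`,
#'   `w_exp`.
#' @param predictions data.frame with columns `api`, `polymer`, `T_K`,
#'   `w_calc`.
#' @return Object of class `deviation_report`: list with `points` (per-point
#'   deviations), `systems` (per-system metrics), `total` (aggregate
#'   metrics), and `median_system_aad`.
#' @export
deviations <- function(exp_table, predictions) {
  need <- function(df, cols, what) {
    if (!all(cols %in% names(df))) {
      stop(what, " needs columns: ", paste(cols, collapse = ", "),
           call. = FALSE)
    }
  }
  need(exp_table, c("api", "polymer", "T_K", "w_exp"), "exp_table")
  need(predictions, c("api", "polymer", "T_K", "w_calc"), "predictions")
  key <- function(df) paste(df$api, df$polymer, signif(df$T_K, 10), sep = "|")
  ke <- key(exp_table)
  kp <- key(predictions)
  missing <- setdiff(ke, kp)
  if (length(missing)) {
    stop("predictions missing for keys: ", paste(missing, collapse = "; "),
         call. = FALSE)
  }
  m <- exp_table
  m$w_calc <- predictions$w_calc[match(ke, kp)]
  m$dw <- m$w_calc - m$w_exp
  m$system <- paste(m$api, m$polymer, sep = "-")

  metrics <- function(dw, w_exp) {
    aard_ok <- all(w_exp != 0)
    data.frame(
      N = length(dw),
      AAD = 100 * mean(abs(dw)),
      AD = 100 * mean(dw),
      AARD = if (aard_ok) 100 * mean(abs(dw / w_exp)) else NA_real_,
      aard_defined = aard_ok)
  }
  per_sys <- do.call(rbind, lapply(split(m, m$system), function(d) {
    cbind(data.frame(system = d$system[1], api = d$api[1],
                     polymer = d$polymer[1]), metrics(d$dw, d$w_exp))
  }))
  rownames(per_sys) <- NULL
  structure(
    list(points = m[, c("system", "api", "polymer", "T_K", "w_exp",
                        "w_calc", "dw")],
         systems = per_sys,
         total = metrics(m$dw, m$w_exp),
         median_system_aad = stats::median(per_sys$AAD)),
    class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf(
    "<deviation_report> %d points, %d systems | AAD = %.2f%%, AD = %+.2f%%",
    x$total$N, nrow(x$systems), x$total$AAD, x$total$AD))
  if (x$total$aard_defined) cat(sprintf(", AARD = %.2f%%", x$total$AARD))
  cat(sprintf("\n  median per-system AAD = %.2f%%\n", x$median_system_aad))
  invisible(x)
}

#' Rank polymer carriers by predicted compatibility with an API
#'
#' Orders polymers by descending predicted API solubility (weight fraction)
#' at a reference temperature. When two entries tie within `band`, a
#' phase-separation-free (no AAPS) polymer outranks an AAPS-positive one;
#' remaining ties break deterministically by name. Grades of one polymer
#' family can be collapsed into a single entry via `grouping` (mean
#' solubility, AAPS if any member shows it).
#'
#' @param predictions data.frame with columns `polymer`, `w_api` and logical
#'   `aaps`, all at the reference temperature.
#' @param T_ref Reference temperature in K (annotation only).
#' @param band Solubility band within which AAPS decides the order.
#' @param grouping Optional named character vector mapping polymer names to
#'   group labels.
#' @return data.frame with columns `rank`, `polymer`, `w_api`, `aaps`,
#'   ordered from most to least compatible; attribute `T_ref`.
#' @export
rank_polymers <- function(predictions, T_ref = 298.15, band = 0.02,
                          grouping = NULL) {
  need <- c("polymer", "w_api", "aaps")
  if (!all(need %in% names(predictions))) {
    stop("predictions needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(predictions) < 2L) {
    stop("ranking needs predictions for at least two polymers", call. = FALSE)
  }
  d <- predictions
  if (!is.null(grouping)) {
    grp <- ifelse(d$polymer %in% names(grouping),
                  grouping[d$polymer], d$polymer)
    d <- do.call(rbind, lapply(split(d, grp), function(g) {
      data.frame(polymer = grp[match(g$polymer[1], d$polymer)],
                 w_api = mean(g$w_api), aaps = any(g$aaps))
    }))
    rownames(d) <- NULL
  }
  # comparator: TRUE when entry i outranks entry j
  before <- function(i, j) {
    dw <- d$w_api[i] - d$w_api[j]
    if (abs(dw) <= band && d$aaps[i] != d$aaps[j]) return(!d$aaps[i])
    if (dw != 0) return(dw > 0)
    d$polymer[i] < d$polymer[j]
  }
  ord <- seq_len(nrow(d))
  for (i in seq_along(ord)[-1]) {        # insertion sort: stable, total order
    j <- i
    while (j > 1L && before(ord[j], ord[j - 1L])) {
      ord[c(j - 1L, j)] <- ord[c(j, j - 1L)]
      j <- j - 1L
    }
  }
  out <- d[ord, , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), polymer = out$polymer,
                    w_api = out$w_api, aaps = out$aaps)
  attr(out, "T_ref") <- T_ref
  out
}
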