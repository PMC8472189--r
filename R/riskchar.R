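# Five-endpoint environmental risk characterization: percentage change rates
# between parents and transformation products, derivative-vs-parent
# improvements, pathway range summaries, and 10-level heat binning.

ENDPOINTS <- c("phytotoxicity", "estrogen_toxicity", "bioconcentration",
               "persistence", "migration")

#' Percentage change of an endpoint score from parent to product
#'
#' \code{100 * (product - parent) / parent}. The sign is kept through parent
#' sign changes (a product can cross zero, e.g. persistence scores), and the
#' arguments are never swapped silently.
#'
#' @param parent,product endpoint scores; \code{parent} must be nonzero.
#' @return change rate in percent.
#' @examples
#' change_rate(67.203, 90.708) # 34.98
#' @export
change_rate <- function(parent, product) {
  if (any(parent == 0)) stop("change rate undefined for parent value 0", call. = FALSE)
  100 * (product - parent) / parent
}

#' Improvement of a derivative's final product over the parent's
#'
#' For the four risk-increasing endpoints (both toxicities, bioconcentration,
#' persistence) a lower score is better, so the improvement is
#' \code{100 * (parent - derivative) / parent}. Migration works the other way
#' (a higher octanol--air partition score means lower long-range transport
#' risk), so there it is \code{100 * (derivative - parent) / parent}.
#'
#' @param parent_final,derivative_final endpoint scores of the two final
#'   products; \code{parent_final} must be nonzero.
#' @param endpoint one of the five endpoint names.
#' @return improvement in percent (positive = derivative is better).
#' @examples
#' improvement(69.928, 56.281, "estrogen_toxicity") # 19.52
#' @export
improvement <- function(parent_final, derivative_final, endpoint) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  if (any(parent_final == 0)) stop("improvement undefined for parent value 0", call. = FALSE)
  if (endpoint == "migration") 100 * (derivative_final - parent_final) / parent_final
  else 100 * (parent_final - derivative_final) / parent_final
}

#' Risk direction of an endpoint change
#'
#' @param endpoint one of the five endpoint names.
#' @param change_pct change rate in percent.
#' @return \code{"risk_increased"}, \code{"risk_decreased"} or
#'   \code{"unchanged"}.
#' @export
risk_direction <- function(endpoint, change_pct) {
  endpoint <- match.arg(endpoint, ENDPOINTS)
  sgn <- sign(change_pct)
  if (endpoint == "migration") sgn <- -sgn
  c("risk_decreased", "unchanged", "risk_increased")[sgn + 2]
}

#' Change records for a degradation chain
#'
#' Builds per-step and final-vs-parent change records for all five endpoints
#' of a parent molecule and its ordered chain of degradation products, from
#' a table of endpoint values.
#'
#' @param parent molecule label of the parent (e.g. \code{"PCB-52"}).
#' @param chain character vector of chain member labels, in order.
#' @param values data.frame with column \code{molecule} plus one column per
#'   endpoint (default: the packaged Table-3 fixture).
#' @return data.frame of change records: molecule, endpoint, parent_value,
#'   product_value, change_pct, and \code{vs} (\code{"parent"} for the
#'   chain-start reference used in the printed table).
#' @examples
#' head(chain_evaluate("PCB-52", paste0("52-", 1:4)))
#' @export
chain_evaluate <- function(parent, chain, values = load_fixture("table3")) {
  if (length(chain) == 0L)
    return(data.frame(molecule = character(0), endpoint = character(0),
                      parent_value = numeric(0), product_value = numeric(0),
                      change_pct = numeric(0), vs = character(0)))
  need <- c(parent, chain)
  miss <- setdiff(need, values$molecule)
  if (length(miss) > 0L) stop("no endpoint values for: ", paste(miss, collapse = ", "),
                              call. = FALSE)
  rows <- list()
  for (m in chain) for (ep in ENDPOINTS) {
    pv <- values[[ep]][values$molecule == parent]
    xv <- values[[ep]][values$molecule == m]
    if (is.na(pv) || is.na(xv)) stop("missing value for ", m, " / ", ep, call. = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      molecule = m, endpoint = ep, parent_value = pv, product_value = xv,
      change_pct = change_rate(pv, xv), vs = "parent", stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-endpoint change-rate ranges of a record set
#'
#' @param records data.frame of change records (see [chain_evaluate()]),
#'   optionally with a grouping column.
#' @param group column name to group by (default none: one summary).
#' @return data.frame with group (if any), endpoint, min_pct, max_pct, n.
#' @export
summarize_changes <- function(records, group = NULL) {
  if (nrow(records) == 0L) {
    warning("empty record set: empty summary", call. = FALSE)
    return(data.frame(endpoint = character(0), min_pct = numeric(0),
                      max_pct = numeric(0), n = integer(0)))
  }
  key <- if (is.null(group)) list(endpoint = records$endpoint)
         else stats::setNames(list(records[[group]], records$endpoint), c(group, "endpoint"))
  agg <- function(f) stats::aggregate(records$change_pct, by = key, FUN = f)
  lo <- agg(min); hi <- agg(max); n <- agg(length)
  out <- lo
  names(out)[ncol(out)] <- "min_pct"
  out$max_pct <- hi$x
  out$n <- as.integer(n$x)
  out
}

#' 10-level heat binning of change-rate magnitudes
#'
#' Each cell of a pathway-by-endpoint summary is scored by its maximum
#' absolute change rate; levels are ten equal-width bins over \[0, global
#' max\], with the global maximum in level 10. An all-zero matrix maps to
#' level 1 everywhere.
#'
#' @param scores numeric matrix (or vector) of cell scores, typically
#'   \code{pmax(abs(min_pct), abs(max_pct))} per cell.
#' @return integer levels, 1..10, same shape as \code{scores}.
#' @examples
#' heat_levels(c(10, 50, 100))
#' @export
heat_levels <- function(scores) {
  s <- abs(scores)
  m <- max(s)
  lv <- if (m == 0) rep(1L, length(s))
        else pmax(1L, pmin(10L, as.integer(ceiling(s / m * 10))))
  if (!is.null(dim(scores))) lv <- array(lv, dim = dim(scores), dimnames = dimnames(scores))
  else names(lv) <- names(scores)
  lv
}

#' Recompute every change-rate cell of the packaged chain table
#'
#' Reads the Table-3 fixture (three PCB parents, three environmentally
#' friendly derivatives, four-step phytodegradation chains each), recomputes
#' all change rates from the value columns, and compares with the printed
#' cells.
#'
#' @param values fixture data.frame (default: packaged Table 3).
#' @return data.frame with one row per (product, endpoint) cell: recomputed
#'   and printed change rates and their absolute difference.
#' @export
recompute_chain_changes <- function(values = load_fixture("table3")) {
  parents <- values$molecule[is.na(values[[paste0(ENDPOINTS[1], "_change")]])]
  rows <- list()
  pv <- NULL
  for (i in seq_len(nrow(values))) {
    m <- values$molecule[i]
    if (m %in% parents) { pv <- values[i, ]; next }
    for (ep in ENDPOINTS) {
      rec <- change_rate(pv[[ep]], values[[ep]][i])
      rows[[length(rows) + 1L]] <- data.frame(
        parent = pv$molecule, molecule = m, endpoint = ep,
        recomputed = rec, printed = values[[paste0(ep, "_change")]][i],
        abs_diff = abs(rec - values[[paste0(ep, "_change")]][i]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
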