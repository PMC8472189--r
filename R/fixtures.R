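# Packaged fixtures: the study's printed data tables, transcribed once into
# plain CSV and schema-checked on load.

fixture_files <- c(
  table1 = "table1_products.csv",
  table2 = "table2_estimates.csv",
  table3 = "table3_chains.csv",
  table4 = "table4_validation.csv",
  bz = "bz_congeners.csv"
)

fixture_check <- function(id, tab) {
  fail <- function(msg) stop("fixture ", id, ": ", msg, call. = FALSE)
  switch(id,
    table1 = {
      if (nrow(tab) != 50L) fail("expected 50 mapping rows")
      if (!all(c("row", "pathway", "parent", "products") %in% names(tab)))
        fail("missing columns")
      if (!all(tab$pathway %in% PATHWAYS)) fail("unknown pathway tag")
    },
    table2 = {
      if (nrow(tab) != 210L) fail("expected 210 congener rows")
      if (!identical(tab$congener, 0:209)) fail("congener column must be 0..209")
      for (col in c("phyto_est", "estro_est"))
        if (anyNA(tab[[col]])) fail(paste("missing estimate in", col))
    },
    table3 = {
      if (nrow(tab) != 30L) fail("expected 30 molecule rows (6 parents + 24 products)")
      need <- c("molecule", ENDPOINTS, paste0(ENDPOINTS, "_change"))
      if (!all(need %in% names(tab))) fail("missing columns")
      if (anyNA(tab[, ENDPOINTS])) fail("missing endpoint value")
    },
    table4 = {
      if (nrow(tab) != 33L) fail("expected 33 molecule rows")
      num <- c("phyto_total", "phyto_est", "phyto_rel_err",
               "estro_total", "estro_est", "estro_rel_err")
      if (!all(num %in% names(tab))) fail("missing columns")
      if (anyNA(tab[, num])) fail("missing numeric cell")
    },
    bz = {
      if (nrow(tab) != 210L) fail("expected 210 congeners")
    })
  invisible(tab)
}

#' Load a packaged fixture table
#'
#' \code{"table1"}: 50 parent-to-product transformation mappings.
#' \code{"table2"}: QSAR-estimated phytotoxicity and estrogen-toxicity
#' scores for all 210 congeners, with observed docking totals where
#' available and a test-set marker. \code{"table3"}: endpoint values and
#' printed change rates for three PCB parents, three environmentally
#' friendly derivatives, and their four-step phytodegradation chains.
#' \code{"table4"}: docking totals vs model estimates for 33 metabolites
#' and derivatives. \code{"bz"}: the congener numbering table.
#'
#' @param table_id fixture identifier.
#' @return schema-validated data.frame.
#' @export
load_fixture <- function(table_id = c("table1", "table2", "table3", "table4", "bz")) {
  table_id <- match.arg(table_id)
  path <- system.file("extdata", fixture_files[[table_id]],
                      package = "pcbtrans", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  fixture_check(table_id, tab)
}

#' Parse a chain table into parent/chain groupings
#'
#' The packaged Table-3 fixture lists each parent row (no printed change
#' rate) followed by its chain members in order.
#'
#' @param values chain fixture (default packaged Table 3).
#' @return list of lists with \code{parent} and \code{chain} labels.
#' @export
fixture_chains <- function(values = load_fixture("table3")) {
  is_parent <- is.na(values[[paste0(ENDPOINTS[1], "_change")]])
  idx <- which(is_parent)
  lapply(seq_along(idx), function(i) {
    to <- if (i < length(idx)) idx[i + 1] - 1L else nrow(values)
    list(parent = values$molecule[idx[i]],
         chain = values$molecule[seq(idx[i] + 1L, to)])
  })
}
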