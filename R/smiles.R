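# SMILES emission for the restricted chemistry handled here: chlorinated
# biphenyls, their OH / MeSO2 metabolites, and chlorobenzoic acids.

ring_tokens <- function(pattern, extra = NULL) {
  # tokens for positions 2..6 of one phenyl ring; `extra` = list(pos=, smi=)
  vapply(2:6, function(pos) {
    grp <- if (pos %in% pattern) "(Cl)"
      else if (!is.null(extra) && pos == extra$pos) paste0("(", extra$smi, ")")
      else ""
    paste0("c", grp)
  }, character(1))
}

assemble_biphenyl <- function(pat_a, pat_b, extra_a = NULL, extra_b = NULL) {
  ta <- ring_tokens(pat_a, extra_a)
  tb <- ring_tokens(pat_b, extra_b)
  # attachment carbons open each ring; closure digit sits on position 6
  ta[5] <- sub("^c", "c1", ta[5])
  tb[5] <- sub("^c", "c2", tb[5])
  paste0("c1(-c2", paste(tb, collapse = ""), ")", paste(ta, collapse = ""))
}

#' SMILES of a congener or transformation product
#'
#' Emits a SMILES string for a PCB congener, an OH-PCB or MeSO2-PCB
#' metabolite, or a chlorobenzoic acid. Chlorine count and locant class are
#' preserved; the string round-trips through [smiles_ring_patterns()].
#'
#' @param x a \code{congener}, a \code{transformation_product} (one row of a
#'   product table, see [transform_products()]), or a congener number.
#' @param ... unused.
#' @return SMILES string.
#' @examples
#' to_smiles(congener(52))
#' @export
to_smiles <- function(x, ...) UseMethod("to_smiles")

#' @export
to_smiles.default <- function(x, ...) to_smiles(as_congener(x))

#' @export
to_smiles.congener <- function(x, ...) assemble_biphenyl(x$ring_a, x$ring_b)

group_smiles <- c(`OH-PCB` = "O", `MeSO2-PCB` = "S(C)(=O)=O")

#' @export
to_smiles.transformation_product <- function(x, ...) {
  switch(x$kind,
    PCB = to_smiles(congener(x$product_number)),
    CBA = {
      pat <- ring_pattern(x$cba_pattern)
      t <- ring_tokens(pat)
      t[5] <- sub("^c", "c1", t[5])
      paste0("c1(C(=O)O)", paste(t, collapse = ""))
    },
    assemble_biphenyl(ring_pattern(x$group_ring), ring_pattern(x$other_ring),
                      extra_a = list(pos = x$group_position, smi = group_smiles[[x$kind]]))
  )
}

#' Recover ring chlorination patterns from an emitted biphenyl SMILES
#'
#' Parses the restricted SMILES grammar produced by [to_smiles()] for PCB
#' congeners and returns the canonical pattern pair; used for round-trip
#' checks.
#'
#' @param smi SMILES string produced by \code{to_smiles()} for a congener.
#' @return list with canonical \code{ring_a}, \code{ring_b}.
#' @export
smiles_ring_patterns <- function(smi) {
  m <- regmatches(smi, regexec("^c1\\(-c2((?:c(?:\\(Cl\\))?){4}c2(?:\\(Cl\\))?)\\)((?:c(?:\\(Cl\\))?){4}c1(?:\\(Cl\\))?)$", smi))[[1]]
  if (length(m) != 3L) stop("not a congener SMILES from to_smiles()", call. = FALSE)
  pat_of <- function(body) {
    toks <- regmatches(body, gregexpr("c[12]?(\\(Cl\\))?", body))[[1]]
    stopifnot(length(toks) == 5L)
    (2:6)[grepl("Cl", toks)]
  }
  canonicalize_rings(pat_of(m[3]), pat_of(m[2]))
}
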