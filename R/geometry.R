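# Conformer generation (Open Babel: 3D embedding + force-field minimization
# + Gasteiger partial charges) and rigid core alignment.

have_obabel <- function() nzchar(Sys.which("obabel"))

parse_mol2 <- function(lines) {
  at <- which(lines == "@<TRIPOS>ATOM")
  bd <- which(lines == "@<TRIPOS>BOND")
  stopifnot(length(at) == 1L, length(bd) == 1L)
  end <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  at_end <- min(end[end > at]) - 1L
  bd_end <- min(end[end > bd]) - 1L
  arec <- read.table(text = lines[(at + 1L):at_end], stringsAsFactors = FALSE)
  brec <- read.table(text = lines[(bd + 1L):bd_end], stringsAsFactors = FALSE,
                     colClasses = c("integer", "integer", "integer", "character"))
  list(
    element = toupper(sub("\\..*$", "", arec$V6)),
    sybyl_type = arec$V6,
    xyz = as.matrix(arec[, 3:5]),
    charge = arec$V9,
    bonds = data.frame(a = brec$V2, b = brec$V3, order = brec$V4,
                       stringsAsFactors = FALSE)
  )
}

#' Embed a molecule in 3D and minimize its energy
#'
#' Generates a single low-energy conformer with Open Babel (MMFF94 force
#' field, deterministic) and assigns Gasteiger partial charges, the
#' iterative partial-equalization scheme. The iteration cap and convergence
#' criterion of the extra minimization pass are configurable; force field
#' and settings are recorded in the conformer metadata.
#'
#' @param smiles SMILES string.
#' @param steps minimization iteration cap (default 10000).
#' @param crit energy convergence criterion passed to the minimizer
#'   (default 0.005).
#' @param minimize run the extra steepest-descent pass after embedding.
#' @param seed recorded in metadata; the embedding itself is deterministic.
#' @return object of class \code{conformer3d}: \code{element},
#'   \code{sybyl_type}, \code{xyz} (Angstrom), \code{charge} (e),
#'   \code{bonds}, \code{meta}.
#' @export
embed_and_minimize <- function(smiles, steps = 10000L, crit = 0.005,
                               minimize = TRUE, seed = 1L) {
  if (!have_obabel()) stop("Open Babel (obabel) not found on PATH", call. = FALSE)
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  args <- c(paste0("-:", smiles), "-omol2", "--gen3d", "--partialcharge", "gasteiger")
  if (minimize) args <- c(args, "--minimize", "--ff", "MMFF94",
                          "--steps", format(steps), "--crit", format(crit))
  out <- suppressWarnings(system2("obabel", shQuote(args), stdout = TRUE, stderr = FALSE))
  if (!any(grepl("^@<TRIPOS>ATOM$", out)))
    stop("embedding failed for SMILES: ", smiles, call. = FALSE)
  mol <- parse_mol2(out)
  if (nrow(mol$xyz) < 2L || any(!is.finite(mol$xyz)))
    stop("embedding produced no valid coordinates", call. = FALSE)
  # mol2 prints charges at 4 decimals; spread the rounding residue so the
  # neutral molecule is exactly neutral
  mol$charge <- mol$charge - sum(mol$charge) / length(mol$charge)
  structure(c(mol, list(meta = list(
    smiles = smiles, force_field = "MMFF94", charges = "gasteiger",
    steps = steps, crit = crit, seed = seed, backend = "openbabel"
  ))), class = "conformer3d")
}

#' @export
print.conformer3d <- function(x, ...) {
  cat(sprintf("conformer3d: %d atoms (%s), %s/%s\n", length(x$element),
              paste0(names(table(x$element)), table(x$element), collapse = " "),
              x$meta$force_field, x$meta$charges))
  invisible(x)
}

# ordered core carbons: for a biphenyl, both rings ordered 1..6 starting at
# the attachment carbon and walking around the ring; for a single benzene
# ring (benzoic acids), the ring ordered from the carbon bearing the
# modified substituent
core_rings <- function(conf) {
  ar <- which(conf$sybyl_type == "C.ar")
  if (length(ar) < 6L) stop("no aromatic core found", call. = FALSE)
  bonds <- conf$bonds
  adj <- lapply(seq_along(conf$element), function(i)
    c(bonds$b[bonds$a == i], bonds$a[bonds$b == i]))
  ar_adj <- lapply(adj, intersect, ar)
  comp_of <- function(start, skip = NULL) {
    seen <- start; queue <- start
    while (length(queue)) {
      nb <- setdiff(unlist(ar_adj[queue]), c(seen, skip))
      seen <- c(seen, nb); queue <- nb
    }
    seen
  }
  walk_ring <- function(start, second) {
    ring <- c(start, second)
    for (step in 3:6) {
      nxt <- setdiff(intersect(ar_adj[[ring[step - 1L]]], comp), ring)
      ring <- c(ring, nxt[1L])
    }
    ring
  }
  if (length(ar) >= 12L) {
    # inter-ring bond = aromatic-aromatic bond that is a bridge
    ab <- bonds[bonds$a %in% ar & bonds$b %in% ar, ]
    for (k in seq_len(nrow(ab))) {
      i <- ab$a[k]; j <- ab$b[k]
      ring_i <- comp_of(i, skip = j)
      if (!(j %in% ring_i) && length(ring_i) == 6L) {
        comp <- ring_i
        r1 <- walk_ring(i, intersect(ar_adj[[i]], comp)[1])
        comp <- comp_of(j, skip = i)
        r2 <- walk_ring(j, intersect(ar_adj[[j]], comp)[1])
        return(list(r1, r2))
      }
    }
    stop("no inter-ring bond found", call. = FALSE)
  }
  # single ring: start at the carbon bonded to a non-ring heavy substituent
  ring <- ar[seq_len(6L)]
  heavy <- which(conf$element != "H")
  start <- ring[vapply(ring, function(i)
    length(setdiff(intersect(adj[[i]], heavy), ar)) > 0L, logical(1))][1]
  if (is.na(start)) start <- ring[1]
  comp <- ring
  list(walk_ring(start, intersect(ar_adj[[start]], comp)[1]))
}

kabsch_rmsd <- function(A, B) {
  # rigid superposition of A onto B (n x 3 each); returns rotation,
  # translation and RMSD
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Arot <- A0 %*% t(R)
  list(R = R, center_from = ca, center_to = cb,
       rmsd = sqrt(mean(rowSums((Arot - B0)^2))))
}

#' Rigidly align a conformer onto a template
#'
#' Least-squares superposition of the aromatic core carbons (12 for a
#' biphenyl, 6 for single-ring acids, mapped to the template's first ring)
#' onto the template. All core-mapping symmetries (ring order and both walk
#' directions) are tried and the mapping with the smallest core RMSD wins.
#'
#' @param conf,template \code{conformer3d} objects; the template must have a
#'   biphenyl core.
#' @return \code{conf} with transformed coordinates and \code{core_rmsd} in
#'   the metadata.
#' @export
align_to_template <- function(conf, template) {
  rc <- core_rings(conf)
  rt <- core_rings(template)
  if (length(rt) < 2L) stop("template must have a biphenyl core", call. = FALSE)
  orientations <- function(r) list(r, r[c(1, 6, 5, 4, 3, 2)])
  maps <- list()
  if (length(rc) == 2L) {
    for (o1 in orientations(rc[[1]])) for (o2 in orientations(rc[[2]]))
      maps <- c(maps, list(c(o1, o2), c(o2, o1)))
    target <- template$xyz[c(rt[[1]], rt[[2]]), , drop = FALSE]
  } else {
    for (o1 in orientations(rc[[1]])) maps <- c(maps, list(o1))
    target <- template$xyz[rt[[1]], , drop = FALSE]
  }
  best <- NULL
  for (m in maps) {
    k <- kabsch_rmsd(conf$xyz[m, , drop = FALSE], target)
    if (is.null(best) || k$rmsd < best$k$rmsd) best <- list(k = k, map = m)
  }
  k <- best$k
  conf$xyz <- sweep(sweep(conf$xyz, 2, k$center_from) %*% t(k$R), 2, k$center_to, "+")
  conf$meta$core_rmsd <- k$rmsd
  conf$meta$aligned <- TRUE
  conf
}
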