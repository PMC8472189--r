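# Ring positions 2..6 (position 1 is the inter-ring bond). Patterns are sorted
# integer vectors; "" or integer(0) is the unsubstituted ring.

#' Validate and normalize a ring substitution pattern
#'
#' A ring pattern is the set of chlorine locants on one phenyl ring of a
#' biphenyl, drawn from positions 2--6 (position 1 carries the inter-ring
#' bond). Accepts an integer vector or a compact digit string such as
#' \code{"25"}.
#'
#' @param x integer vector of locants in 2..6, or a digit string.
#' @return sorted integer vector of unique locants (possibly empty).
#' @examples
#' ring_pattern("25")
#' ring_pattern(c(5, 2))
#' @export
ring_pattern <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- if (nzchar(x)) as.integer(strsplit(x, "")[[1]]) else integer(0)
  }
  x <- as.integer(x)
  if (anyNA(x) || any(x < 2L | x > 6L))
    stop("ring positions must lie in {2,...,6}", call. = FALSE)
  sort(unique(x))
}

pattern_string <- function(p) paste(p, collapse = "")

# reflection through the ring axis: 2<->6, 3<->5, 4 fixed (conformationally
# equivalent because of rotation about the inter-ring bond)
flip_ring <- function(p) sort(c(8L, 8L, 8L, 8L, 8L)[p - 1L] - p)

# lexicographic order on sorted locant vectors (shorter prefix wins)
pattern_lt <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

ring_min <- function(p) {
  f <- flip_ring(p)
  if (pattern_lt(f, p)) f else p
}

#' Canonicalize a pair of ring patterns under biphenyl symmetry
#'
#' The symmetry group has eight elements: the two per-ring reflections
#' (2/6 and 3/5 exchange, equivalent conformationally through rotation about
#' the inter-ring bond) and the interchange of the two rings. The canonical
#' representative is the lexicographically smallest image with
#' \code{ring_a <= ring_b}. Idempotent and constant on each orbit.
#'
#' @param ring_a,ring_b ring patterns (see [ring_pattern()]).
#' @return list with sorted canonical \code{ring_a}, \code{ring_b}.
#' @examples
#' canonicalize_rings("45", "25") # same orbit as ("34","25")
#' @export
canonicalize_rings <- function(ring_a, ring_b) {
  a <- ring_min(ring_pattern(ring_a))
  b <- ring_min(ring_pattern(ring_b))
  if (pattern_lt(b, a)) list(ring_a = b, ring_b = a) else list(ring_a = a, ring_b = b)
}

# -- Ballschmiter-Zell numbering ---------------------------------------------

# Display-name orientation: the ring with more chlorines is unprimed
# (tie: lexicographically smaller pattern unprimed). Locant sort key is
# 2*position + primed so that n < n' < n+1.
name_orientation <- function(ring_a, ring_b) {
  a <- ring_min(ring_a); b <- ring_min(ring_b)
  if (length(b) > length(a) || (length(a) == length(b) && pattern_lt(b, a)))
    list(unprimed = b, primed = a)
  else list(unprimed = a, primed = b)
}

locant_key <- function(unprimed, primed) sort(c(2L * unprimed, 2L * primed + 1L))

key_to_name <- function(k) {
  if (length(k) == 0L) return("biphenyl")
  paste(ifelse(k %% 2L == 0L, k %/% 2L, paste0((k - 1L) %/% 2L, "'")), collapse = ",")
}

#' Derive the 209-congener numbering from first principles
#'
#' Enumerates the 210 symmetry classes of chlorination patterns (biphenyl
#' included as number 0), names each under the standard prime convention,
#' and orders them by homolog class and ascending locant sequence. The
#' historical Ballschmiter--Zell assignment for congeners 107--109 deviates
#' from strict locant order and is applied as a fixed exception
#' (107 = 2,3,3',4',5; 108 = 2,3,3',4,5'; 109 = 2,3,3',4,6).
#'
#' The packaged table (\code{inst/extdata/bz_congeners.csv}) was generated by
#' this function; a test asserts they agree.
#'
#' @return data.frame with columns \code{number}, \code{name}, \code{ring_a},
#'   \code{ring_b} (compact digit strings), \code{n_cl}.
#' @export
derive_bz_numbering <- function() {
  subsets <- lapply(0:31, function(m) (2:6)[bitwAnd(m, 2L^(0:4)) > 0L])
  seen <- new.env(parent = emptyenv())
  cls <- vector("list", 210L); n_cls <- 0L
  for (a in subsets) for (b in subsets) {
    k <- canonicalize_rings(a, b)
    ks <- paste(pattern_string(k$ring_a), pattern_string(k$ring_b), sep = "|")
    if (is.null(seen[[ks]])) {
      assign(ks, TRUE, envir = seen)
      n_cls <- n_cls + 1L
      cls[[n_cls]] <- k
    }
  }
  cls <- cls[seq_len(n_cls)]
  keys <- lapply(cls, function(k) {
    o <- name_orientation(k$ring_a, k$ring_b)
    locant_key(o$unprimed, o$primed)
  })
  n_cl <- vapply(cls, function(k) length(k$ring_a) + length(k$ring_b), integer(1))
  keystr <- vapply(keys, function(k) paste(sprintf("%02d", k), collapse = ""), character(1))
  ord <- order(n_cl, keystr)
  cls <- cls[ord]; keys <- keys[ord]; n_cl <- n_cl[ord]
  number <- 0:209
  nm <- vapply(keys, key_to_name, character(1))
  # historical exception: BZ order of the 2,3,3',4,x pentachloro triple
  i <- match(c("2,3,3',4,5'", "2,3,3',4,6", "2,3,3',4',5"), nm)
  stopifnot(identical(number[i], c(107L, 108L, 109L)))
  number[i] <- c(108L, 109L, 107L)
  out <- data.frame(
    number = number,
    name = nm,
    ring_a = vapply(cls, function(k) pattern_string(k$ring_a), character(1)),
    ring_b = vapply(cls, function(k) pattern_string(k$ring_b), character(1)),
    n_cl = n_cl,
    stringsAsFactors = FALSE
  )
  out[order(out$number), , drop = FALSE]
}

.pcb_cache <- new.env(parent = emptyenv())

#' The packaged Ballschmiter--Zell congener table
#'
#' @return data.frame of 210 rows (congener 0 = biphenyl) with columns
#'   \code{number}, \code{name}, \code{ring_a}, \code{ring_b}, \code{n_cl}.
#' @export
congener_table <- function() {
  if (is.null(.pcb_cache$table)) {
    path <- system.file("extdata", "bz_congeners.csv", package = "pcbtrans", mustWork = TRUE)
    tab <- utils::read.csv(path, colClasses = c("integer", "character", "character", "character", "integer"))
    stopifnot(nrow(tab) == 210L, identical(tab$number, 0:209))
    .pcb_cache$table <- tab
    idx <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(tab)))
      assign(paste(tab$ring_a[i], tab$ring_b[i], sep = "|"), tab$number[i], envir = idx)
    .pcb_cache$index <- idx
  }
  .pcb_cache$table
}

#' Congener number of a chlorination pattern pair
#'
#' Canonicalizes the pair and looks it up in the packaged table; total over
#' all 1024 pattern pairs.
#'
#' @inheritParams canonicalize_rings
#' @return integer in 0..209.
#' @examples
#' congener_number("25", "25") # PCB-52
#' @export
congener_number <- function(ring_a, ring_b) {
  congener_table()
  k <- canonicalize_rings(ring_a, ring_b)
  get(paste(pattern_string(k$ring_a), pattern_string(k$ring_b), sep = "|"),
      envir = .pcb_cache$index)
}

#' Ring patterns of a congener number
#'
#' Inverse of [congener_number()] up to canonical form.
#'
#' @param number integer in 0..209.
#' @return list with \code{ring_a}, \code{ring_b} (sorted integer vectors).
#' @export
congener_patterns <- function(number) {
  number <- as.integer(number)
  if (length(number) != 1L || is.na(number) || number < 0L || number > 209L)
    stop("congener number must lie in 0..209", call. = FALSE)
  tab <- congener_table()
  i <- match(number, tab$number)
  list(ring_a = ring_pattern(tab$ring_a[i]), ring_b = ring_pattern(tab$ring_b[i]))
}

#' Construct a congener object
#'
#' @param x congener number (0..209), or a ring pattern with \code{ring_b}.
#' @param ring_b second ring pattern when \code{x} is the first.
#' @return object of class \code{congener}: canonical ring patterns, number,
#'   homolog class \code{n_cl}, and display name.
#' @examples
#' congener(52)
#' congener("25", "25")
#' @export
congener <- function(x, ring_b = NULL) {
  if (is.null(ring_b) && is.numeric(x) && length(x) == 1L) {
    pats <- congener_patterns(x)
    n <- as.integer(x)
  } else {
    pats <- canonicalize_rings(x, ring_b)
    n <- congener_number(pats$ring_a, pats$ring_b)
  }
  tab <- congener_table()
  structure(
    list(ring_a = pats$ring_a, ring_b = pats$ring_b, number = n,
         n_cl = length(pats$ring_a) + length(pats$ring_b),
         name = tab$name[match(n, tab$number)]),
    class = "congener"
  )
}

#' @export
print.congener <- function(x, ...) {
  cat(sprintf("PCB-%d (%s), %d Cl\n", x$number, x$name, x$n_cl))
  invisible(x)
}

#' @export
format.congener <- function(x, ...) sprintf("PCB-%d", x$number)

as_congener <- function(x) {
  if (inherits(x, "congener")) x
  else if (is.numeric(x)) congener(x)
  else if (is.character(x) && grepl("^PCB-\\d+$", x)) congener(as.integer(sub("PCB-", "", x)))
  else stop("cannot interpret ", deparse(x), " as a congener", call. = FALSE)
}

# ortho/meta/para class of a locant relative to the inter-ring bond
site_class <- function(pos) c(`2` = "ortho", `3` = "meta", `4` = "para",
                              `5` = "meta", `6` = "ortho")[as.character(pos)]
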