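# Rule engines for the four environmental transformation pathways:
#   plant degradation      -> chlorobenzoic acids (ring opening)
#   microbial aerobic      -> OH-PCBs (meta/para hydroxylation)
#   microbial anaerobic    -> reductive single dechlorination
#   biometabolism          -> MeSO2-PCBs (meta/para methylsulfonylation)
#   photodegradation       -> sequential dechlorination (ortho-first)

PATHWAYS <- c("plant", "microbial_aerobic", "microbial_anaerobic",
              "biometabolism", "photodegradation")

product_row <- function(parent, pathway, kind, name, alias = NA_character_,
                        product_number = NA_integer_, cba_pattern = NA_character_,
                        group_ring = NA_character_, other_ring = NA_character_,
                        group_position = NA_integer_, site_class = NA_character_,
                        steps = NA_integer_) {
  data.frame(parent = parent, pathway = pathway, kind = kind, name = name,
             alias = alias, product_number = product_number,
             cba_pattern = cba_pattern, group_ring = group_ring,
             other_ring = other_ring, group_position = group_position,
             site_class = site_class, steps = steps, stringsAsFactors = FALSE)
}

empty_products <- function() {
  data.frame(parent = integer(0), pathway = character(0), kind = character(0),
             name = character(0), alias = character(0),
             product_number = integer(0), cba_pattern = character(0),
             group_ring = character(0), other_ring = character(0),
             group_position = integer(0), site_class = character(0),
             steps = integer(0), stringsAsFactors = FALSE)
}

finish_products <- function(rows) {
  out <- if (length(rows) == 0L) empty_products()
         else do.call(rbind, rows)
  out <- out[!duplicated(out$name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("product_table", "data.frame")
  out
}

# one row as an object to_smiles() understands
product_structure <- function(products, i) {
  x <- as.list(products[i, , drop = FALSE])
  class(x) <- "transformation_product"
  x
}

#' SMILES for every row of a product table
#' @param products result of a pathway generator such as [plant_degrade()].
#' @return character vector of SMILES, one per product row.
#' @export
product_smiles <- function(products) {
  vapply(seq_len(nrow(products)), function(i) to_smiles(product_structure(products, i)),
         character(1))
}

# Naming of an added -OH / -MeSO2 group: the parent congener number is kept;
# the group locant is minimized over the flip of its own ring (Table 1 writes
# 3-MeSO2-CB110, i.e. the ring is renumbered so the group, not the chlorines,
# takes the low locant); a prime marks the ring that is primed in the parent
# name (more-chlorinated ring unprimed, ties broken lexicographically). The
# alias is the same name with the prime toggled: two Table 1 rows use the
# opposite orientation and the alias makes name matching structural.
group_product <- function(parent_congener, pathway, kind, ring_label, pos) {
  o <- name_orientation(parent_congener$ring_a, parent_congener$ring_b)
  ring <- if (ring_label == "unprimed") o$unprimed else o$primed
  other <- if (ring_label == "unprimed") o$primed else o$unprimed
  pos_f <- flip_ring(pos)
  named_pos <- pos
  named_ring <- ring
  if (pos_f < pos || (pos_f == pos && pattern_lt(flip_ring(ring), ring))) {
    named_pos <- pos_f
    named_ring <- flip_ring(ring)
  }
  prime <- if (ring_label == "primed") "'" else ""
  alt <- if (ring_label == "primed") "" else "'"
  grp <- if (kind == "OH-PCB") "OH" else "MeSO2"
  product_row(
    parent = parent_congener$number, pathway = pathway, kind = kind,
    name = sprintf("%d%s-%s-CB%d", named_pos, prime, grp, parent_congener$number),
    alias = sprintf("%d%s-%s-CB%d", named_pos, alt, grp, parent_congener$number),
    group_ring = pattern_string(named_ring),
    other_ring = pattern_string(ring_min(other)),
    group_position = named_pos, site_class = site_class(named_pos)
  )
}

# distinct free meta/para sites of both rings, deduplicated by product
# structure (symmetric rings and equal ring pairs collapse)
free_sites <- function(cg, positions = c(3L, 4L, 5L)) {
  o <- name_orientation(cg$ring_a, cg$ring_b)
  seen <- character(0)
  out <- list()
  for (ring_label in c("unprimed", "primed")) {
    ring <- if (ring_label == "unprimed") o$unprimed else o$primed
    other <- if (ring_label == "unprimed") o$primed else o$unprimed
    for (pos in setdiff(positions, ring)) {
      # structural key: group ring canonicalized jointly with the group
      k1 <- paste(pos, pattern_string(ring), pattern_string(ring_min(other)))
      k2 <- paste(flip_ring(pos), pattern_string(flip_ring(ring)), pattern_string(ring_min(other)))
      key <- min(k1, k2)
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(ring_label = ring_label, pos = pos)
    }
  }
  out
}

#' Plant degradation: ring opening to chlorobenzoic acids
#'
#' Dioxygenase attack opens the less-chlorinated ring; the product is the
#' chlorobenzoic acid carrying the surviving ring's chlorine pattern
#' (carboxyl at position 1). On a tie in ring chlorine counts both outcomes
#' are emitted and deduplicated.
#'
#' @param x congener, congener number, or \code{"PCB-n"} string.
#' @return product table (one row per distinct product).
#' @examples
#' plant_degrade(3) # 4-CBA
#' @export
plant_degrade <- function(x) {
  cg <- as_congener(x)
  na <- length(cg$ring_a); nb <- length(cg$ring_b)
  survivors <- if (na > nb) list(cg$ring_a) else if (nb > na) list(cg$ring_b)
               else list(cg$ring_a, cg$ring_b)
  rows <- lapply(survivors, function(p) {
    p <- ring_min(p)
    nm <- if (length(p) == 0L) "benzoic acid" else paste0(paste(p, collapse = ","), "-CBA")
    product_row(cg$number, "plant", "CBA", nm, cba_pattern = pattern_string(p))
  })
  finish_products(rows)
}

#' Microbial aerobic degradation: meta/para hydroxylation
#'
#' One hydroxyl is added at each unsubstituted meta (3/5) or para (4)
#' position; para products are flagged as the preferred attack site.
#'
#' @inheritParams plant_degrade
#' @return product table with a \code{preferred} column (para sites).
#' @export
aerobic_hydroxylate <- function(x) {
  cg <- as_congener(x)
  rows <- lapply(free_sites(cg), function(s)
    group_product(cg, "microbial_aerobic", "OH-PCB", s$ring_label, s$pos))
  out <- finish_products(rows)
  out$preferred <- !is.na(out$site_class) & out$site_class == "para"
  out
}

#' Biometabolism: meta/para methylsulfonylation
#'
#' One methylsulfonyl group is added at each unsubstituted meta or para
#' position, mirroring the MeSO2-PCB metabolites formed via epoxide and
#' methylthio intermediates.
#'
#' @inheritParams plant_degrade
#' @export
biometabolize <- function(x) {
  cg <- as_congener(x)
  rows <- lapply(free_sites(cg), function(s)
    group_product(cg, "biometabolism", "MeSO2-PCB", s$ring_label, s$pos))
  finish_products(rows)
}

single_removals <- function(cg) {
  # all distinct single-chlorine removals with the removal site class
  out <- list()
  seen <- integer(0)
  for (ring in c("a", "b")) {
    pat <- if (ring == "a") cg$ring_a else cg$ring_b
    other <- if (ring == "a") cg$ring_b else cg$ring_a
    for (p in pat) {
      n <- congener_number(setdiff(pat, p), other)
      if (n %in% seen) {
        i <- which(vapply(out, function(r) r$number == n, logical(1)))
        out[[i]]$sites <- union(out[[i]]$sites, site_class(p))
      } else {
        seen <- c(seen, n)
        out[[length(out) + 1L]] <- list(number = n, sites = site_class(p))
      }
    }
  }
  out
}

#' Microbial anaerobic degradation: reductive single dechlorination
#'
#' All single-chlorine-removal products, annotated with the removal site
#' class; meta and para removals are the main microbial reduction sites and
#' are flagged preferred, ortho removals are retained unflagged.
#'
#' @inheritParams plant_degrade
#' @export
anaerobic_dechlorinate <- function(x) {
  cg <- as_congener(x)
  if (cg$n_cl == 0L) return(finish_products(list()))
  rows <- lapply(single_removals(cg), function(r)
    product_row(cg$number, "microbial_anaerobic", "PCB",
                sprintf("PCB-%d", r$number), product_number = r$number,
                site_class = paste(sort(r$sites), collapse = "/")))
  out <- finish_products(rows)
  out$preferred <- grepl("meta|para", out$site_class)
  out
}

#' Photodegradation: sequential dechlorination reachability
#'
#' Congeners reachable by removing 1..\code{max_steps} chlorines one at a
#' time. Photolysis removes ortho chlorines first; each product records the
#' minimal step count and the removal-site classes along a preference-first
#' (ortho > para > meta) path.
#'
#' @inheritParams plant_degrade
#' @param max_steps maximum number of sequential dechlorination steps (>= 1).
#' @export
photodechlorinate <- function(x, max_steps = 1L) {
  cg <- as_congener(x)
  stopifnot(max_steps >= 1L)
  pref <- c(ortho = 1L, para = 2L, meta = 3L)
  frontier <- list(list(number = cg$number, path = character(0)))
  visited <- cg$number
  rows <- list()
  for (step in seq_len(max_steps)) {
    nxt <- list()
    for (node in frontier) {
      rem <- single_removals(congener(node$number))
      rank <- vapply(rem, function(r) min(pref[strsplit(r$sites, "/")[[1]]]), integer(1))
      for (r in rem[order(rank)]) {
        if (r$number %in% visited) next
        visited <- c(visited, r$number)
        path <- c(node$path, sort(strsplit(r$sites, "/")[[1]])[1])
        rows[[length(rows) + 1L]] <- product_row(
          cg$number, "photodegradation", "PCB", sprintf("PCB-%d", r$number),
          product_number = r$number, site_class = paste(path, collapse = ">"),
          steps = step)
        nxt[[length(nxt) + 1L]] <- list(number = r$number, path = path)
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  finish_products(rows)
}

#' Transformation products of a congener under one pathway
#'
#' Dispatcher over the four pathway engines.
#'
#' @inheritParams plant_degrade
#' @param pathway one of \code{"plant"}, \code{"microbial_aerobic"},
#'   \code{"microbial_anaerobic"}, \code{"biometabolism"},
#'   \code{"photodegradation"}.
#' @param max_steps passed to [photodechlorinate()].
#' @export
transform_products <- function(x, pathway, max_steps = 4L) {
  pathway <- match.arg(pathway, PATHWAYS)
  switch(pathway,
    plant = plant_degrade(x),
    microbial_aerobic = aerobic_hydroxylate(x),
    microbial_anaerobic = anaerobic_dechlorinate(x),
    biometabolism = biometabolize(x),
    photodegradation = photodechlorinate(x, max_steps = max_steps))
}

#' Verify the packaged parent-to-product mapping table
#'
#' Re-derives every listed transformation product from its parent and
#' pathway and checks set membership: a listed name matches when it equals a
#' generated product's canonical name, its prime-toggled alias, or (for
#' dechlorination) the product congener number. Listed products are observed
#' ones, so membership rather than set equality is asserted.
#'
#' @param mappings data.frame with columns \code{pathway}, \code{parent},
#'   \code{products} (\code{;}-separated); default the packaged Table-1
#'   fixture via [load_fixture()].
#' @param max_steps photodegradation search depth.
#' @return data.frame with one row per mapping row: parent, pathway, listed
#'   products, and \code{matched}.
#' @export
verify_product_mappings <- function(mappings = load_fixture("table1"), max_steps = 4L) {
  if (nrow(mappings) == 0L)
    return(data.frame(row = integer(0), pathway = character(0),
                      parent = character(0), products = character(0),
                      matched = logical(0), stringsAsFactors = FALSE))
  res <- lapply(seq_len(nrow(mappings)), function(i) {
    parent <- mappings$parent[i]
    if (!grepl("^PCB-\\d+$", parent)) stop("unknown parent name: ", parent, call. = FALSE)
    gen <- transform_products(parent, mappings$pathway[i], max_steps = max_steps)
    listed <- strsplit(mappings$products[i], ";", fixed = TRUE)[[1]]
    ok <- vapply(listed, function(nm) any(gen$name == nm | gen$alias %in% nm), logical(1))
    data.frame(row = mappings$row[i], pathway = mappings$pathway[i], parent = parent,
               products = mappings$products[i], matched = all(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}
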