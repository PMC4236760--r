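## Brute-force discovery of emulation morphisms: enumerate total species
## maps (optionally constrained to map triplet motifs onto triplet motifs,
## directly or dually), derive the induced reaction map, and keep the maps
## whose induced homomorphism satisfies the net-stoichiomorphism condition
## on the unit-rate networks.  By the change-of-rates corollary every such
## morphism extends to an emulation for any rate assignment of the target
## (rates copied).

#' Enumerate total species maps between two networks
#'
#' Maps are produced in deterministic lexicographic order (source species
#' in network order; the last species varies fastest over the target
#' species in network order).  With `respect_triplets = TRUE` only maps
#' that send each source triplet onto a target triplet are produced,
#' either directly (`x0 -> x0_hat, x1 -> x1_hat, x2 -> x2_hat`) or dually
#' (`x0 -> x2_hat, x1 -> x1_hat, x2 -> x0_hat`).
#'
#' @param src,tgt networks built by [crn()].
#' @param respect_triplets constrain maps to whole-triplet images.
#' @param src_triplets,tgt_triplets triplet bindings (data frames with
#'   columns `node`, `s0`, `s1`, `s2`); default taken from the networks'
#'   [triplet_bindings()].
#' @param max_maps cap on the number of enumerated maps; when reached the
#'   result carries attribute `truncated = TRUE`.
#' @return a list of named character species maps.
#' @export
enumerate_species_maps <- function(src, tgt, respect_triplets = FALSE,
                                   src_triplets = NULL, tgt_triplets = NULL,
                                   max_maps = 1e6) {
  stopifnot(inherits(src, "crn"), inherits(tgt, "crn"), max_maps > 0)
  if (!respect_triplets) {
    ns <- n_species(src); nt <- n_species(tgt)
    if (ns == 0L)
      return(structure(list(stats::setNames(character(0), character(0))),
                       truncated = FALSE))
    if (nt == 0L) return(structure(list(), truncated = FALSE))
    total <- nt ^ ns
    truncated <- total > max_maps
    n_out <- min(total, max_maps)
    out <- vector("list", n_out)
    idx <- rep(1L, ns)                      # odometer, last digit fastest
    for (k in seq_len(n_out)) {
      out[[k]] <- stats::setNames(tgt$species[idx], src$species)
      j <- ns
      while (j >= 1L) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nt) break
        idx[j] <- 1L; j <- j - 1L
      }
    }
    return(structure(out, truncated = truncated))
  }
  if (is.null(src_triplets)) src_triplets <- triplet_bindings(src)
  if (is.null(tgt_triplets)) tgt_triplets <- triplet_bindings(tgt)
  k <- nrow(src_triplets); nt <- nrow(tgt_triplets)
  if (k == 0L)
    return(structure(list(stats::setNames(character(0), character(0))),
                     truncated = FALSE))
  nchoice <- 2L * nt                        # target triplet x {direct, dual}
  total <- nchoice ^ k
  truncated <- total > max_maps
  n_out <- min(total, max_maps)
  out <- vector("list", n_out)
  idx <- rep(1L, k)
  for (q in seq_len(n_out)) {
    nm <- character(0); val <- character(0)
    for (i in seq_len(k)) {
      tt <- tgt_triplets[((idx[i] - 1L) %/% 2L) + 1L, ]
      dual <- (idx[i] - 1L) %% 2L == 1L
      nm <- c(nm, unlist(src_triplets[i, c("s0", "s1", "s2")]))
      val <- c(val, if (dual) c(tt$s2, tt$s1, tt$s0)
               else c(tt$s0, tt$s1, tt$s2))
    }
    out[[q]] <- stats::setNames(val, nm)
    j <- k
    while (j >= 1L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= nchoice) break
      idx[j] <- 1L; j <- j - 1L
    }
  }
  structure(out, truncated = truncated)
}

#' Reaction map induced by a species map
#'
#' For each source reaction `rho ->{k} pi`, looks for the unique target
#' reaction equal to `m_S(rho) -> m_S(pi)` (with equal rate unless
#' `unit_rate = TRUE`).  Failure is a value, not an error: the result
#' names the first source reaction without an image.
#'
#' @param m_S named character species map.
#' @param src,tgt networks built by [crn()].
#' @param unit_rate ignore rates when matching.
#' @return a list with `ok`, the integer `map` (when `ok`), and
#'   `failed_at` (the first unmatched source reaction index, when not).
#' @export
induced_reaction_map <- function(m_S, src, tgt, unit_rate = FALSE) {
  tgt_keys <- vapply(tgt$reactions, function(r)
    paste(complex_key(r$reactants), complex_key(r$products), sep = " -> "),
    character(1))
  tgt_rates <- vapply(tgt$reactions, `[[`, numeric(1), "rate")
  map <- integer(n_reactions(src))
  for (j in seq_len(n_reactions(src))) {
    r <- src$reactions[[j]]
    key <- paste(complex_key(apply_complex_map(m_S, r$reactants)),
                 complex_key(apply_complex_map(m_S, r$products)),
                 sep = " -> ")
    hit <- which(tgt_keys == key)
    if (!unit_rate) hit <- hit[tgt_rates[hit] == r$rate]
    if (length(hit) != 1L)
      return(list(ok = FALSE, map = NULL, failed_at = j))
    map[j] <- hit
  }
  list(ok = TRUE, map = map, failed_at = NA_integer_)
}

#' Search for emulation morphisms between two networks
#'
#' Implements the unit-rate homomorphism strategy: replace all rates by 1,
#' enumerate species maps ([enumerate_species_maps()]), keep those whose
#' induced homomorphism exists and satisfies the (exact, integer)
#' net-stoichiomorphism condition.  Every returned morphism is a
#' homomorphism and stoichiomorphism between the unit-rate networks and
#' therefore, by the change-of-rates corollary, extends to a kinetic
#' emulation for *every* rate assignment of the target, with the source
#' simply copying the target rates.
#'
#' With `homomorphic = FALSE` an exhaustive mode is available that also
#' enumerates free reaction maps for every species map (bounded by
#' `max_maps` total candidates) and keeps the pairs passing the
#' reactant-morphism and rate-weighted stoichiomorphism checks on the
#' networks *as given* (rates kept, since non-homomorphic emulations may
#' trade rates against stoichiometry); this finds non-homomorphic
#' emulations but grows very quickly.
#'
#' @inheritParams enumerate_species_maps
#' @param homomorphic restrict to induced (homomorphic) reaction maps.
#' @return a list of [crn_morphism()] objects between the unit-rate
#'   networks, in enumeration order, with attribute `truncated`.
#' @export
find_emulations <- function(src, tgt, respect_triplets = FALSE,
                            src_triplets = NULL, tgt_triplets = NULL,
                            max_maps = 1e6, homomorphic = TRUE) {
  stopifnot(inherits(src, "crn"), inherits(tgt, "crn"))
  usrc <- unit_rate_crn(src); utgt <- unit_rate_crn(tgt)
  maps <- enumerate_species_maps(src, tgt, respect_triplets,
                                 src_triplets, tgt_triplets, max_maps)
  out <- list()
  n_cand <- 0L
  truncated <- isTRUE(attr(maps, "truncated"))
  for (m_S in maps) {
    if (homomorphic) {
      ind <- induced_reaction_map(m_S, usrc, utgt, unit_rate = TRUE)
      if (!ind$ok) next
      m <- crn_morphism(usrc, utgt, species = m_S, reactions = ind$map)
      if (is_net_stoichiomorphism(m)$holds)
        out[[length(out) + 1L]] <- m
    } else {
      nr <- n_reactions(usrc); nt <- n_reactions(utgt)
      rmaps <- if (nr == 0L) list(integer(0)) else {
        grid <- do.call(expand.grid, rep(list(seq_len(nt)), nr))
        lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
      }
      for (m_R in rmaps) {
        n_cand <- n_cand + 1L
        if (n_cand > max_maps) { truncated <- TRUE; break }
        m <- crn_morphism(src, tgt, species = m_S, reactions = m_R)
        if (is_reactant_morphism(m)$holds &&
            is_stoichiomorphism(m)$holds)
          out[[length(out) + 1L]] <- m
      }
      if (truncated) break
    }
  }
  structure(out, truncated = truncated)
}
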