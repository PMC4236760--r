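## Network morphisms and their static checks: reactant morphism,
## homomorphism, stoichiomorphism, net stoichiomorphism, composition, and
## change-of-rates lifting.  All conditions are matrix identities over the
## characteristic 0-1 matrices of the species and reaction maps.

#' Construct a morphism between two reaction networks
#'
#' A network morphism is a pair of total maps: a species map `m_S` from
#' source to target species and a reaction map `m_R` from source to target
#' reactions.  The reaction map may be given explicitly (by target reaction
#' index, following the source reaction order) or derived from the species
#' map with `homomorphic = TRUE`, in which case each source reaction
#' `rho ->{k} pi` must have exactly the image reaction
#' `m_S(rho) ->{k} m_S(pi)` present in the target.
#'
#' @param source,target networks built by [crn()].
#' @param species named character vector mapping every source species to a
#'   target species.
#' @param reactions integer vector of target reaction indices, one per
#'   source reaction, or `NULL` with `homomorphic = TRUE`.
#' @param homomorphic derive the reaction map from the species map.
#' @return an object of class `crn_morphism` with fields `source`,
#'   `target`, `species_map`, `reaction_map`.
#' @export
crn_morphism <- function(source, target, species, reactions = NULL,
                         homomorphic = is.null(reactions)) {
  stopifnot(inherits(source, "crn"), inherits(target, "crn"))
  species <- stats::setNames(as.character(species), names(species))
  missing <- setdiff(source$species, names(species))
  if (length(missing))
    stop("species map is not total on the source; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  species <- species[source$species]
  outside <- setdiff(unname(species), target$species)
  if (length(outside))
    stop("species map image outside the target: ",
         paste(outside, collapse = ", "), call. = FALSE)
  if (homomorphic && is.null(reactions)) {
    ind <- induced_reaction_map(species, source, target)
    if (!ind$ok)
      stop("species map does not induce a homomorphism: source reaction ",
           ind$failed_at, " (",
           format_reaction(source$reactions[[ind$failed_at]], digits = 7),
           ") has no image reaction in the target", call. = FALSE)
    reactions <- ind$map
  }
  reactions <- as.integer(reactions)
  if (length(reactions) != n_reactions(source))
    stop("reaction map must assign a target reaction to every source ",
         "reaction", call. = FALSE)
  if (n_reactions(source) &&
      (any(is.na(reactions)) || any(reactions < 1L) ||
       any(reactions > n_reactions(target))))
    stop("reaction map indices out of range", call. = FALSE)
  structure(list(source = source, target = target, species_map = species,
                 reaction_map = reactions),
            class = "crn_morphism")
}

#' @export
print.crn_morphism <- function(x, ...) {
  cat("Network morphism: ", n_species(x$source), " species / ",
      n_reactions(x$source), " reactions  ->  ", n_species(x$target),
      " species / ", n_reactions(x$target), " reactions\n", sep = "")
  cat("species map: ",
      paste(names(x$species_map), unname(x$species_map), sep = " -> ",
            collapse = ", "), "\n", sep = "")
  cat("reaction map:", paste(seq_along(x$reaction_map), x$reaction_map,
                             sep = " -> ", collapse = ", "), "\n")
  invisible(x)
}

#' Fibers (inverse images) of a map
#'
#' @param m a named vector viewed as a map from `names(m)` to its values.
#' @param codomain the codomain elements; defaults to the values occurring
#'   in `m`.
#' @return a named list: for each codomain element, the (possibly empty)
#'   set of domain elements mapping to it.
#' @export
fibers <- function(m, codomain = unique(unname(m))) {
  out <- lapply(codomain, function(b) names(m)[unname(m) == b])
  stats::setNames(out, codomain)
}

## characteristic 0-1 matrix of a map given as index vector or named vector
char_matrix <- function(idx, n_dom, n_cod, dimnames = NULL) {
  mm <- matrix(0L, n_dom, n_cod, dimnames = dimnames)
  if (n_dom) mm[cbind(seq_len(n_dom), idx)] <- 1L
  mm
}

species_char_matrix <- function(m) {
  idx <- match(unname(m$species_map), m$target$species)
  char_matrix(idx, n_species(m$source), n_species(m$target),
              list(m$source$species, m$target$species))
}

reaction_char_matrix <- function(m) {
  char_matrix(m$reaction_map, n_reactions(m$source), n_reactions(m$target))
}

check_result <- function(lhs, rhs, tol = 0, max_witnesses = 10L,
                         dim_labels = c("row", "col")) {
  d <- abs(lhs - rhs)
  bad <- which(d > tol, arr.ind = TRUE)
  holds <- nrow(bad) == 0L
  max_residual <- if (length(d)) max(d) else 0
  if (nrow(bad) > max_witnesses) bad <- bad[seq_len(max_witnesses), ,
                                            drop = FALSE]
  witnesses <- data.frame(
    row = if (nrow(bad)) rownames(lhs)[bad[, 1]] %||%
      as.character(bad[, 1]) else character(0),
    col = if (nrow(bad)) (colnames(lhs)[bad[, 2]] %||%
      as.character(bad[, 2])) else character(0),
    lhs = lhs[bad], rhs = rhs[bad],
    stringsAsFactors = FALSE)
  names(witnesses)[1:2] <- dim_labels
  structure(list(holds = holds, witnesses = witnesses,
                 max_residual = max_residual),
            class = "crn_check")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.crn_check <- function(x, ...) {
  cat(if (x$holds) "check holds" else "check FAILS", sep = "")
  if (!is.null(x$max_residual))
    cat(" (max residual ", format(x$max_residual, digits = 4), ")",
        sep = "")
  cat("\n")
  if (!x$holds && nrow(x$witnesses)) {
    cat("witnesses (first ", nrow(x$witnesses), "):\n", sep = "")
    print(x$witnesses, row.names = FALSE)
  }
  invisible(x)
}

#' Static morphism checks
#'
#' `is_reactant_morphism` checks, in exact integer arithmetic, that each
#' source reaction's reactant complex maps onto its image reaction's
#' reactant complex: as matrices, `t(mS) %*% rho == rho_hat %*% t(mR)`.
#'
#' `is_homomorphism` checks that the reaction map is fully determined by
#' the species map: every source reaction `rho ->{k} pi` maps to exactly
#' `m_S(rho) ->{k} m_S(pi)` (mapped complexes and equal rate).
#'
#' `is_stoichiomorphism` checks preservation of instantaneous stoichiometry
#' over reaction fibers: for each source species `s` and target reaction
#' `r_hat`, the sum of `phi(s, r)` over the fiber of `r_hat` equals
#' `phi_hat(m_S(s), r_hat)`; as matrices, `phi %*% mR == mS %*% phi_hat`,
#' compared with absolute tolerance `tol` on the rate-weighted entries.
#'
#' `is_net_stoichiomorphism` is the same condition on the rate-free net
#' stoichiometry `eta`, checked exactly in integer arithmetic; on networks
#' with all-unit rates it coincides with the stoichiomorphism condition.
#'
#' A morphism that is both a reactant morphism and a stoichiomorphism is a
#' kinetic emulation: the source reproduces every target trajectory from
#' pulled-back initial conditions.
#'
#' @param m a [crn_morphism()].
#' @param tol absolute tolerance for the rate-weighted comparison.
#' @return an object of class `crn_check`: `holds` flag, a data frame of
#'   up to 10 failing `witnesses` with both sides' values, and the maximum
#'   residual.
#' @export
is_reactant_morphism <- function(m) {
  stopifnot(inherits(m, "crn_morphism"))
  src <- stoich_matrices(m$source); tgt <- stoich_matrices(m$target)
  mS <- species_char_matrix(m); mR <- reaction_char_matrix(m)
  lhs <- t(mS) %*% src$reactant
  rhs <- tgt$reactant %*% t(mR)
  check_result(lhs, rhs, tol = 0,
               dim_labels = c("target_species", "source_reaction"))
}

#' @rdname is_reactant_morphism
#' @export
is_homomorphism <- function(m) {
  stopifnot(inherits(m, "crn_morphism"))
  wit <- data.frame(source_reaction = integer(0), field = character(0),
                    lhs = character(0), rhs = character(0),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_reactions(m$source))) {
    r <- m$source$reactions[[j]]
    rh <- m$target$reactions[[m$reaction_map[j]]]
    img_rho <- apply_complex_map(m$species_map, r$reactants)
    img_pi <- apply_complex_map(m$species_map, r$products)
    add <- function(field, lhs, rhs)
      rbind(wit, data.frame(source_reaction = j, field = field,
                            lhs = lhs, rhs = rhs, stringsAsFactors = FALSE))
    if (!identical(complex_key(img_rho), complex_key(rh$reactants)))
      wit <- add("reactants", format_complex(img_rho),
                 format_complex(rh$reactants))
    if (!identical(complex_key(img_pi), complex_key(rh$products)))
      wit <- add("products", format_complex(img_pi),
                 format_complex(rh$products))
    if (r$rate != rh$rate)
      wit <- add("rate", format(r$rate), format(rh$rate))
    if (nrow(wit) >= 10L) break
  }
  structure(list(holds = nrow(wit) == 0L, witnesses = wit,
                 max_residual = NULL),
            class = "crn_check")
}

#' @rdname is_reactant_morphism
#' @export
is_stoichiomorphism <- function(m, tol = 1e-12) {
  stopifnot(inherits(m, "crn_morphism"))
  src <- stoich_matrices(m$source); tgt <- stoich_matrices(m$target)
  mS <- species_char_matrix(m); mR <- reaction_char_matrix(m)
  lhs <- src$instantaneous %*% mR
  rhs <- mS %*% tgt$instantaneous
  colnames(lhs) <- colnames(rhs) <- if (n_reactions(m$target))
    paste0("r", seq_len(n_reactions(m$target))) else character(0)
  check_result(lhs, rhs, tol = tol,
               dim_labels = c("source_species", "target_reaction"))
}

#' @rdname is_reactant_morphism
#' @export
is_net_stoichiomorphism <- function(m) {
  stopifnot(inherits(m, "crn_morphism"))
  src <- stoich_matrices(m$source); tgt <- stoich_matrices(m$target)
  mS <- species_char_matrix(m); mR <- reaction_char_matrix(m)
  lhs <- src$net %*% mR
  rhs <- mS %*% tgt$net
  colnames(lhs) <- colnames(rhs) <- if (n_reactions(m$target))
    paste0("r", seq_len(n_reactions(m$target))) else character(0)
  check_result(lhs, rhs, tol = 0,
               dim_labels = c("source_species", "target_reaction"))
}

#' Compose two morphisms
#'
#' @param m1 morphism from network A to network B.
#' @param m2 morphism from network B to network C; `m1$target` must equal
#'   `m2$source` structurally.
#' @return the componentwise composite morphism from A to C.
#' @export
compose_morphisms <- function(m1, m2) {
  stopifnot(inherits(m1, "crn_morphism"), inherits(m2, "crn_morphism"))
  if (!crn_equal(m1$target, m2$source))
    stop("m1's target and m2's source are different networks",
         call. = FALSE)
  species <- stats::setNames(unname(m2$species_map[m1$species_map]),
                             names(m1$species_map))
  reactions <- m2$reaction_map[m1$reaction_map]
  crn_morphism(m1$source, m2$target, species = species,
               reactions = reactions)
}

#' Lift a change of rates across a stoichiomorphism
#'
#' A change of rates reassigns the rate of every target reaction while
#' leaving complexes untouched.  Given a stoichiomorphism `m` and new
#' target rates `k_hat_prime`, each source reaction `rho ->{k} pi` whose
#' image has old rate `k_hat` is re-rated to `k * k_hat_prime / k_hat`; the
#' same species and reaction maps between the re-rated networks are again a
#' stoichiomorphism (and a reactant morphism or homomorphism if `m` was
#' one), so emulation is preserved under any rate choice for the target.
#' In the homomorphism case (`k == k_hat`) the new source rates are simply
#' copies of the new target rates.
#'
#' @param m a [crn_morphism()] passing [is_stoichiomorphism()].
#' @param new_rates positive numeric vector, one rate per target reaction
#'   (in target reaction order).
#' @return a `crn_morphism` between the re-rated source and target.
#' @export
change_of_rates_lift <- function(m, new_rates) {
  stopifnot(inherits(m, "crn_morphism"))
  new_rates <- as.numeric(new_rates)
  if (length(new_rates) != n_reactions(m$target))
    stop("need one new rate per target reaction (",
         n_reactions(m$target), ")", call. = FALSE)
  if (any(!is.finite(new_rates)) || any(new_rates <= 0))
    stop("all new rates must be strictly positive", call. = FALSE)
  old_rates <- vapply(m$target$reactions, `[[`, numeric(1), "rate")
  new_target <- m$target
  for (j in seq_along(new_target$reactions))
    new_target$reactions[[j]]$rate <- new_rates[j]
  new_source <- m$source
  for (j in seq_along(new_source$reactions)) {
    jh <- m$reaction_map[j]
    new_source$reactions[[j]]$rate <-
      new_source$reactions[[j]]$rate * new_rates[jh] / old_rates[jh]
  }
  crn_morphism(new_source, new_target, species = m$species_map,
               reactions = m$reaction_map)
}
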