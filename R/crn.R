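## Chemical reaction network data model: species, complexes, reactions,
## stoichiometric matrices, homomorphic projection, and the plain-text
## `.crn` format.

.token_re <- "^[A-Za-z_][A-Za-z0-9_]*$"

is_species_token <- function(x) {
  is.character(x) & nzchar(x) & grepl(.token_re, x)
}

#' Build a complex (multiset of species)
#'
#' A complex assigns a nonnegative integer multiplicity to each species; it
#' is the left- or right-hand side of a reaction.  The empty complex (no
#' species) is legal and is used for inflow/outflow reactions in open
#' systems.
#'
#' @param x a named numeric vector of nonnegative integer multiplicities
#'   (zero entries are dropped), an already-built complex, or a string in
#'   `.crn` complex syntax such as `"2A + B"` or `"0"`.
#' @return a named integer vector of class `crn_complex`, canonicalized:
#'   only strictly positive multiplicities, sorted by species name.
#' @examples
#' as_complex("2A + B")
#' as_complex(c(B = 1, A = 2))
#' as_complex("0")            # the empty complex
#' @export
as_complex <- function(x) {
  if (inherits(x, "crn_complex")) return(x)
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    return(parse_complex(x))
  }
  if (length(x) == 0L) x <- stats::setNames(integer(0), character(0))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("complex must be a named vector of multiplicities", call. = FALSE)
  if (any(x < 0) || any(x != round(x)))
    stop("complex multiplicities must be nonnegative integers", call. = FALSE)
  bad <- names(x)[!is_species_token(names(x))]
  if (length(bad))
    stop("invalid species token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  x <- x[x > 0]
  if (length(x)) {
    x <- tapply(as.integer(x), names(x), sum)   # collapse repeated names
    x <- x[order(names(x))]
  }
  out <- stats::setNames(as.integer(x), names(x) %||% character(0))
  class(out) <- "crn_complex"
  out
}

parse_complex <- function(text) {
  text <- trimws(text)
  if (text == "0" || text == "")
    return(as_complex(stats::setNames(integer(0), character(0))))
  terms <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  if (any(!nzchar(terms)))
    stop("malformed complex: '", text, "'", call. = FALSE)
  mult <- integer(length(terms))
  name <- character(length(terms))
  term_re <- "^([0-9]+)?\\s*\\*?\\s*([A-Za-z_][A-Za-z0-9_]*)$"
  for (i in seq_along(terms)) {
    mm <- regmatches(terms[i], regexec(term_re, terms[i]))[[1]]
    if (length(mm) != 3L)
      stop("malformed complex term: '", terms[i], "'", call. = FALSE)
    mult[i] <- if (nzchar(mm[2])) as.integer(mm[2]) else 1L
    name[i] <- mm[3]
    if (mult[i] < 1L)
      stop("multiplicity must be a positive integer in '", terms[i], "'",
           call. = FALSE)
  }
  as_complex(stats::setNames(mult, name))
}

format_complex <- function(cx) {
  if (length(cx) == 0L) return("0")
  paste(ifelse(cx > 1L, paste0(cx, unname(names(cx))), names(cx)),
        collapse = " + ")
}

#' @export
print.crn_complex <- function(x, ...) {
  cat(format_complex(x), "\n")
  invisible(x)
}

complex_key <- function(cx) {
  if (length(cx) == 0L) return("0")
  paste(cx, names(cx), sep = "*", collapse = "+")
}

#' Build a reaction
#'
#' A reaction `rho ->{k} pi` has a reactant complex, a product complex, and
#' a strictly positive mass-action rate constant (units s^-1 M^(1-order)
#' where the order is the total reactant multiplicity).
#'
#' @param reactants,products complexes, in any form accepted by
#'   [as_complex()].
#' @param rate strictly positive rate constant.
#' @return an object of class `crn_reaction`.
#' @examples
#' reaction("2A + B", "B + C", 1.5)
#' reaction("0", "A", 2)     # inflow
#' @export
reaction <- function(reactants, products, rate = 1) {
  reactants <- as_complex(reactants)
  products <- as_complex(products)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0)
    stop("rate must be a strictly positive number in reaction ",
         format_complex(reactants), " -> ", format_complex(products),
         call. = FALSE)
  structure(list(reactants = reactants, products = products,
                 rate = as.numeric(rate)),
            class = "crn_reaction")
}

format_reaction <- function(r, digits = 17) {
  paste0(format_complex(r$reactants), " ->{",
         trimws(formatC(r$rate, digits = digits, format = "g")), "} ",
         format_complex(r$products))
}

#' @export
print.crn_reaction <- function(x, ...) {
  cat(format_reaction(x, digits = 7), "\n")
  invisible(x)
}

reaction_order <- function(r) sum(r$reactants)

#' Build a chemical reaction network
#'
#' Assembles species and reactions into a validated network.  Reactions
#' sharing both their reactant and product complexes are kinetically
#' equivalent under mass action and are merged into a single reaction with
#' the summed rate (a message records each merge).  The species order is
#' the explicit `species` argument order, with any species that appear only
#' in complexes appended in first-mention order (reactants before products,
#' reactions in list order); all stoichiometric matrices use this order.
#'
#' @param reactions a list of [reaction()] objects.
#' @param species optional character vector fixing the leading species
#'   order; may include species not mentioned in any reaction.
#' @return an object of class `crn` with elements `species` (character)
#'   and `reactions` (list of `crn_reaction`).
#' @examples
#' crn(list(reaction("A", "B", 1), reaction("A", "B", 2)))  # merged, rate 3
#' @export
crn <- function(reactions = list(), species = character()) {
  if (inherits(reactions, "crn_reaction")) reactions <- list(reactions)
  stopifnot(is.list(reactions))
  reactions <- lapply(reactions, function(r) {
    if (!inherits(r, "crn_reaction"))
      stop("all elements of 'reactions' must be crn_reaction objects",
           call. = FALSE)
    r
  })
  species <- as.character(species)
  bad <- species[!is_species_token(species)]
  if (length(bad))
    stop("invalid species token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(species))
    stop("duplicated species in species list", call. = FALSE)

  ## append complex-only species in first-mention order
  for (r in reactions) {
    for (nm in c(names(r$reactants), names(r$products)))
      if (!nm %in% species) species <- c(species, nm)
  }

  ## merge duplicate (reactants, products) pairs by summing rates
  if (length(reactions)) {
    keys <- vapply(reactions, function(r)
      paste(complex_key(r$reactants), complex_key(r$products), sep = " -> "),
      character(1))
    if (anyDuplicated(keys)) {
      ukeys <- unique(keys)
      merged <- vector("list", length(ukeys))
      for (i in seq_along(ukeys)) {
        idx <- which(keys == ukeys[i])
        r <- reactions[[idx[1]]]
        if (length(idx) > 1L) {
          r$rate <- sum(vapply(reactions[idx], `[[`, numeric(1), "rate"))
          message("merged ", length(idx), " duplicate reactions ",
                  ukeys[i], " (rates summed)")
        }
        merged[[i]] <- r
      }
      reactions <- merged
    }
  }
  structure(list(species = species, reactions = reactions), class = "crn")
}

n_species <- function(net) length(net$species)
n_reactions <- function(net) length(net$reactions)

#' @export
print.crn <- function(x, ...) {
  cat("Chemical reaction network: ", n_species(x), " species, ",
      n_reactions(x), " reactions\n", sep = "")
  cat("species:", paste(x$species, collapse = " "), "\n")
  for (r in x$reactions) cat("  ", format_reaction(r, digits = 7), "\n")
  invisible(x)
}

#' @export
summary.crn <- function(object, ...) {
  sm <- stoich_matrices(object)
  cat("Chemical reaction network\n")
  cat("  species:    ", n_species(object), "\n")
  cat("  reactions:  ", n_reactions(object), "\n")
  if (n_reactions(object)) {
    ord <- vapply(object$reactions, reaction_order, numeric(1))
    cat("  orders:     ", paste(sort(unique(ord)), collapse = ", "), "\n")
    cat("  rate range: ",
        paste(signif(range(vapply(object$reactions, `[[`, numeric(1),
                                  "rate")), 6), collapse = " .. "), "\n")
    cons <- all(colSums(sm$net) == 0L)
    cat("  multiplicity-conserving:", cons, "\n")
  }
  invisible(sm)
}

#' Structural equality of two networks
#'
#' Networks are equal when they have the same species set and the same set
#' of reactions (reactant complex, product complex, rate), regardless of
#' the order in which species or reactions are listed.
#'
#' @param a,b networks built by [crn()].
#' @param tol absolute tolerance on rate comparison.
#' @return `TRUE` or `FALSE`.
#' @export
crn_equal <- function(a, b, tol = 0) {
  stopifnot(inherits(a, "crn"), inherits(b, "crn"))
  if (!setequal(a$species, b$species)) return(FALSE)
  if (n_reactions(a) != n_reactions(b)) return(FALSE)
  key <- function(r) paste(complex_key(r$reactants), complex_key(r$products),
                           sep = " -> ")
  ka <- vapply(a$reactions, key, character(1))
  kb <- vapply(b$reactions, key, character(1))
  if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb))
    return(FALSE)
  idx <- match(ka, kb)
  ra <- vapply(a$reactions, `[[`, numeric(1), "rate")
  rb <- vapply(b$reactions, `[[`, numeric(1), "rate")[idx]
  all(abs(ra - rb) <= tol)
}

complex_to_vec <- function(cx, species) {
  v <- stats::setNames(integer(length(species)), species)
  if (length(cx)) {
    missing <- setdiff(names(cx), species)
    if (length(missing))
      stop("species not in network: ", paste(missing, collapse = ", "),
           call. = FALSE)
    v[names(cx)] <- cx
  }
  v
}

#' Stoichiometric matrices of a network
#'
#' Returns the reactant matrix `rho(s, r)`, product matrix `pi(s, r)`, net
#' stoichiometry `eta = pi - rho`, and the instantaneous stoichiometry
#' `phi(s, r) = k_r * eta(s, r)` (net stoichiometry scaled by the rate
#' constant, the state-independent factor of the mass-action ODE).  All are
#' |S| x |R| matrices indexed by the network's species and reaction orders.
#'
#' @param net a network built by [crn()].
#' @return a list with integer matrices `reactant`, `product`, `net` and a
#'   double matrix `instantaneous`, plus the `rates` vector.
#' @export
stoich_matrices <- function(net) {
  stopifnot(inherits(net, "crn"))
  ns <- n_species(net); nr <- n_reactions(net)
  dn <- list(net$species,
             if (nr) paste0("r", seq_len(nr)) else character(0))
  rho <- matrix(0L, ns, nr, dimnames = dn)
  pi_ <- matrix(0L, ns, nr, dimnames = dn)
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    rho[, j] <- complex_to_vec(r$reactants, net$species)
    pi_[, j] <- complex_to_vec(r$products, net$species)
  }
  rates <- vapply(net$reactions, `[[`, numeric(1), "rate")
  eta <- pi_ - rho
  phi <- eta * rep(rates, each = ns)
  dimnames(phi) <- dn
  list(reactant = rho, product = pi_, net = eta, instantaneous = phi,
       rates = rates)
}

#' Map a complex through a species map
#'
#' Applies a (possibly non-injective) species map to a complex; species
#' collapsing to the same image have their multiplicities summed (the fiber
#' sum).
#'
#' @param m_S a named character vector: names are source species, values
#'   target species.
#' @param cx a complex ([as_complex()]).
#' @return the image complex over the target species.
#' @examples
#' apply_complex_map(c(y0 = "x0", z2 = "x0"), as_complex("y0 + z2"))  # 2 x0
#' @export
apply_complex_map <- function(m_S, cx) {
  cx <- as_complex(cx)
  if (length(cx) == 0L) return(cx)
  unmapped <- setdiff(names(cx), names(m_S))
  if (length(unmapped))
    stop("species not in the domain of the map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  as_complex(stats::setNames(as.integer(cx), unname(m_S[names(cx)])))
}

#' Homomorphic projection of a network through a species map
#'
#' Collapses the network along a total species map: the target has species
#' `m_S(S)` and, for every source reaction `rho ->{k} pi`, the image
#' reaction `m_S(rho) ->{k} m_S(pi)`.  Source reactions with identical
#' image reactions (same image complexes and rate) collapse to a single
#' target reaction; the rate is *not* summed, because the image is the set
#' of image reactions.  Two source reactions whose images share both
#' complexes but disagree on the rate would not form a valid network and
#' raise an error.
#'
#' The returned morphism maps each source reaction to its image and is
#' always a surjective homomorphism (an epimorphism).
#'
#' @param net source network.
#' @param m_S named character vector, total on `net$species`.
#' @return a list with elements `network` (the projected [crn()]) and
#'   `morphism` (the projection [crn_morphism()]).
#' @export
homomorphic_projection <- function(net, m_S) {
  stopifnot(inherits(net, "crn"))
  missing <- setdiff(net$species, names(m_S))
  if (length(missing))
    stop("species map is not total; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- m_S[!is_species_token(m_S)]
  if (length(bad))
    stop("invalid target species token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  tgt_species <- unique(unname(m_S[net$species]))

  nr <- n_reactions(net)
  imgs <- vector("list", nr)
  keys <- character(nr)
  for (j in seq_len(nr)) {
    r <- net$reactions[[j]]
    img <- reaction(apply_complex_map(m_S, r$reactants),
                    apply_complex_map(m_S, r$products), r$rate)
    imgs[[j]] <- img
    keys[j] <- paste(complex_key(img$reactants), complex_key(img$products),
                     sep = " -> ")
  }
  ukeys <- unique(keys)
  m_R <- match(keys, ukeys)
  tgt_reactions <- vector("list", length(ukeys))
  for (i in seq_along(ukeys)) {
    idx <- which(keys == ukeys[i])
    rates <- vapply(imgs[idx], `[[`, numeric(1), "rate")
    if (any(rates != rates[1]))
      stop("source reactions project onto the same image complexes with ",
           "different rates (", ukeys[i], "); the image is not a valid ",
           "network", call. = FALSE)
    tgt_reactions[[i]] <- imgs[[idx[1]]]
  }
  target <- crn(tgt_reactions, species = tgt_species)
  morphism <- crn_morphism(net, target,
                           species = m_S[net$species], reactions = m_R)
  list(network = target, morphism = morphism)
}

## ---- `.crn` text format -------------------------------------------------

#' Read and write the plain-text `.crn` reaction-list format
#'
#' One reaction per line, `complex ->{rate} complex`, where a complex is
#' `0` (empty) or `+`-separated terms `n*Name`, `nName` or `Name`.  `#`
#' starts a comment; an optional header line `species: A B C` fixes the
#' species order.  `parse_crn(write_crn(net))` reproduces `net` exactly.
#'
#' @param text a single string or character vector of lines (`parse_crn`),
#'   or a file path (`read_crn`).
#' @param net a network built by [crn()].
#' @param path file path for `read_crn`.
#' @return `parse_crn`/`read_crn` return a [crn()]; `write_crn` returns a
#'   single string (invisibly writes to `path` when given).
#' @examples
#' net <- parse_crn("2A + B ->{1.5} B + C")
#' cat(write_crn(net))
#' @export
parse_crn <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  species <- character()
  reactions <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (grepl("^species\\s*:", ln)) {
      sp <- strsplit(trimws(sub("^species\\s*:", "", ln)), "\\s+")[[1]]
      sp <- sp[nzchar(sp)]
      species <- c(species, sp)
      next
    }
    parts <- strsplit(ln, "->", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop("syntax error on line ", i, ": '", ln, "'", call. = FALSE)
    mm <- regmatches(parts[2], regexec(
      "^\\s*\\{\\s*([^}]+)\\s*\\}(.*)$", parts[2]))[[1]]
    if (length(mm) != 3L)
      stop("syntax error (missing '{rate}') on line ", i, ": '", ln, "'",
           call. = FALSE)
    rate <- suppressWarnings(as.numeric(trimws(mm[2])))
    if (is.na(rate))
      stop("invalid rate on line ", i, ": '", trimws(mm[2]), "'",
           call. = FALSE)
    if (rate <= 0)
      stop("rate must be positive on line ", i, call. = FALSE)
    r <- tryCatch(reaction(parse_complex(parts[1]), parse_complex(mm[3]), rate),
                  error = function(e)
                    stop("line ", i, ": ", conditionMessage(e),
                         call. = FALSE))
    reactions[[length(reactions) + 1L]] <- r
  }
  crn(reactions, species = species)
}

#' @rdname parse_crn
#' @export
write_crn <- function(net, path = NULL) {
  stopifnot(inherits(net, "crn"))
  lines <- c(paste("species:", paste(net$species, collapse = " ")),
             vapply(net$reactions, format_reaction, character(1)))
  out <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(out))
  }
  out
}

#' @rdname parse_crn
#' @export
read_crn <- function(path) {
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  parse_crn(readLines(path, warn = FALSE))
}

## internal: replace every rate by 1 (distinct reactions stay distinct
## because a valid network never holds two reactions with equal complexes)
unit_rate_crn <- function(net) {
  net$reactions <- lapply(net$reactions, function(r) { r$rate <- 1; r })
  net
}
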