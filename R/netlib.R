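## Bundled networks, morphisms and counterexamples, plus seeded random
## generators for property testing.  Everything is built in code; the
## Figure-6-style counterexample pairs are reconstructions from their
## caption formulas and are flagged as such.

#' Bundled example networks and morphisms
#'
#' Available fixtures:
#' \describe{
#'   \item{`am`}{Approximate Majority: the three-species, four-reaction
#'     bistable population switch with unit rates,
#'     `x_0 + x_2 -> x_0 + x_1`, `x_2 + x_0 -> x_2 + x_1`,
#'     `x_0 + x_1 -> 2 x_0`, `x_2 + x_1 -> 2 x_2`.  Also carried as an
#'     influence network: a single node whose high side activates itself
#'     and whose low side inhibits itself; its compilation is exactly the
#'     reaction list above.}
#'   \item{`mi`}{Mutual Inhibition: two nodes, each activating itself and
#'     inhibiting the other (unit rates); compiles to 6 species and 8
#'     reactions.}
#'   \item{`triplet`}{the single-node triplet motif (same influence
#'     network as `am`).}
#'   \item{`mi_to_am_morphism`}{the dual-collapse morphism from compiled
#'     MI onto AM: `y` maps directly (`y_i -> x_i`) and `z` dually
#'     (`z_0 -> x_2, z_1 -> x_1, z_2 -> x_0`), with the induced
#'     homomorphic reaction map (every AM reaction has a fiber of two MI
#'     reactions).}
#'   \item{`fig6a`}{two disjoint copies of a one-reaction network mapped
#'     componentwise onto it: a homomorphism and stoichiomorphism.}
#'   \item{`fig6b`}{`s0 -> s1` and `s0 -> s2` both mapped onto
#'     `s0h -> s1h`: a homomorphism that fails the stoichiomorphism
#'     condition with fiber sum -2 against -1 on `(s0, r1)`.}
#'   \item{`fig6d`}{`s0 -> s1 + s2` mapped onto `s0h -> 2 s1h`: a
#'     homomorphism that fails the stoichiomorphism condition with 1
#'     against 2 on `(s1, r1)`.}
#'   \item{`fig6f`}{`s0 -> s0 + 2 s1` and `s0 -> s0` (rate k) both mapped
#'     onto `s0h ->{2k} s0h + s1h`: a reactant morphism and
#'     stoichiomorphism that is not a homomorphism (rates and products
#'     traded against stoichiometry).}
#' }
#'
#' @param name one of the fixture names above.
#' @return a list of class `crn_fixture` with fields `name`, `network`
#'   (a [crn()], [influence_network()] or [crn_morphism()]; influence
#'   fixtures also carry the compiled `crn`), `provenance` (free text) and
#'   `reconstructed` (`TRUE` for fixtures rebuilt from figure-caption
#'   formulas rather than stated reaction lists).
#' @export
builtin_fixture <- function(name) {
  fx <- switch(
    name,
    am = {
      net <- crn(list(
        reaction("x_0 + x_2", "x_0 + x_1"),
        reaction("x_2 + x_0", "x_2 + x_1"),
        reaction("x_0 + x_1", "2x_0"),
        reaction("x_2 + x_1", "2x_2")),
        species = c("x_0", "x_1", "x_2"))
      attr(net, "triplets") <- data.frame(node = "x", s0 = "x_0",
                                          s1 = "x_1", s2 = "x_2",
                                          stringsAsFactors = FALSE)
      list(network = net,
           influence = .am_influence(),
           provenance = "three-species approximate-majority switch",
           reconstructed = FALSE)
    },
    triplet = {
      inet <- .am_influence()
      list(network = inet, crn = compile_influence(inet),
           provenance = "single-node triplet motif (one activator, one inhibitor)",
           reconstructed = FALSE)
    },
    mi = {
      inet <- influence_network(
        nodes = c("y", "z"),
        edges = data.frame(
          from = c("y", "y", "z", "z"),
          polarity = "high",
          to = c("y", "z", "z", "y"),
          mode = c("activate", "inhibit", "activate", "inhibit"),
          stringsAsFactors = FALSE))
      list(network = inet, crn = compile_influence(inet),
           provenance = "two-node mutual-inhibition network",
           reconstructed = FALSE)
    },
    mi_to_am_morphism = {
      mi <- builtin_fixture("mi")$crn
      am <- builtin_fixture("am")$network
      m <- crn_morphism(mi, am, species = c(
        y_0 = "x_0", y_1 = "x_1", y_2 = "x_2",
        z_0 = "x_2", z_1 = "x_1", z_2 = "x_0"), homomorphic = TRUE)
      list(network = m,
           provenance = "dual-collapse emulation morphism MI -> AM",
           reconstructed = FALSE)
    },
    fig6a = {
      src <- crn(list(reaction("s0", "s1"), reaction("s2", "s3")))
      tgt <- crn(list(reaction("s0h", "s1h")))
      m <- crn_morphism(src, tgt, species = c(
        s0 = "s0h", s1 = "s1h", s2 = "s0h", s3 = "s1h"),
        reactions = c(1L, 1L))
      list(network = m,
           provenance = "two disjoint copies mapped onto one copy",
           reconstructed = TRUE)
    },
    fig6b = {
      src <- crn(list(reaction("s0", "s1"), reaction("s0", "s2")))
      tgt <- crn(list(reaction("s0h", "s1h")))
      m <- crn_morphism(src, tgt, species = c(
        s0 = "s0h", s1 = "s1h", s2 = "s1h"), reactions = c(1L, 1L))
      list(network = m,
           provenance = "homomorphism that is not a stoichiomorphism (-2 vs -1)",
           reconstructed = TRUE)
    },
    fig6d = {
      src <- crn(list(reaction("s0", "s1 + s2")))
      tgt <- crn(list(reaction("s0h", "2s1h")))
      m <- crn_morphism(src, tgt, species = c(
        s0 = "s0h", s1 = "s1h", s2 = "s1h"), reactions = 1L)
      list(network = m,
           provenance = "homomorphism that is not a stoichiomorphism (1 vs 2)",
           reconstructed = TRUE)
    },
    fig6f = {
      k <- 1
      src <- crn(list(reaction("s0", "s0 + 2s1", k),
                      reaction("s0", "s0", k)))
      tgt <- crn(list(reaction("s0h", "s0h + s1h", 2 * k)))
      m <- crn_morphism(src, tgt, species = c(s0 = "s0h", s1 = "s1h"),
                        reactions = c(1L, 1L))
      list(network = m,
           provenance = "reactant morphism and stoichiomorphism, not a homomorphism",
           reconstructed = TRUE)
    },
    stop("unknown fixture: ", name, call. = FALSE))
  structure(c(list(name = name), fx), class = "crn_fixture")
}

.am_influence <- function() {
  influence_network(
    nodes = "x",
    edges = data.frame(from = "x", polarity = c("high", "low"), to = "x",
                       mode = c("activate", "inhibit"),
                       stringsAsFactors = FALSE))
}

#' @export
print.crn_fixture <- function(x, ...) {
  cat("Fixture '", x$name, "' (", x$provenance,
      if (x$reconstructed) "; reconstructed from caption formulas", ")\n",
      sep = "")
  print(x$network)
  invisible(x)
}

#' Fixture names available from [builtin_fixture()]
#' @return character vector of names.
#' @export
builtin_fixture_names <- function() {
  c("am", "mi", "triplet", "mi_to_am_morphism",
    "fig6a", "fig6b", "fig6d", "fig6f")
}

## evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random reaction network
#'
#' Deterministic for a fixed seed.  Reactant and product complexes draw
#' each species' multiplicity from `0:max_stoich` (biased towards sparse
#' complexes); duplicate (reactants, products) pairs merge by rate
#' summation as in [crn()]; rates are uniform on (0.1, 2].
#'
#' @param seed integer seed.
#' @param n_species,n_reactions network size.
#' @param max_stoich maximum stoichiometric multiplicity.
#' @return a [crn()].
#' @export
random_crn <- function(seed, n_species = 4, n_reactions = 6,
                       max_stoich = 2) {
  stopifnot(n_species >= 1, n_reactions >= 0, max_stoich >= 1)
  species <- paste0("s", seq_len(n_species))
  with_seed(seed, {
    reactions <- vector("list", n_reactions)
    draw_complex <- function() {
      mult <- stats::rbinom(n_species, max_stoich, 0.5 / max_stoich)
      as_complex(stats::setNames(mult, species))
    }
    for (j in seq_len(n_reactions))
      reactions[[j]] <- reaction(draw_complex(), draw_complex(),
                                 stats::runif(1, 0.1, 2))
    suppressMessages(crn(reactions, species = species))
  })
}

#' Random state on a network's species
#'
#' Componentwise uniform on `[0, scale]`, deterministic for a fixed seed.
#' With `zero_prob > 0` each species is independently clamped to exactly 0
#' with that probability, producing boundary states.
#'
#' @param seed integer seed.
#' @param net a [crn()].
#' @param scale upper bound of the uniform draw.
#' @param zero_prob probability of zeroing each coordinate.
#' @return named nonnegative state vector.
#' @export
random_state <- function(seed, net, scale = 2, zero_prob = 0) {
  stopifnot(inherits(net, "crn"), scale > 0, zero_prob >= 0,
            zero_prob <= 1)
  with_seed(seed, {
    v <- stats::runif(n_species(net), 0, scale)
    if (zero_prob > 0)
      v[stats::runif(n_species(net)) < zero_prob] <- 0
    stats::setNames(v, net$species)
  })
}
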