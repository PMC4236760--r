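# Static morphism checks: reactant morphism, homomorphism,
# stoichiomorphism, net stoichiomorphism, composition, change of rates.

test_that("fibers partition the domain", {
  m <- mi_to_am()
  f <- fibers(m$species_map, m$target$species)
  expect_setequal(f$x_1, c("y_1", "z_1"))
  expect_setequal(f$x_0, c("y_0", "z_2"))
  expect_setequal(unlist(f), names(m$species_map))
  idf <- fibers(c(a = "a", b = "b"))
  expect_equal(lengths(idf), c(a = 1L, b = 1L))
  cf <- fibers(c(a = "t", b = "t", c = "t"))
  expect_setequal(cf$t, c("a", "b", "c"))
})

test_that("morphism construction validates totality and ranges", {
  am <- am_net()
  expect_error(crn_morphism(mi_net(), am, species = c(y_0 = "x_0")),
               "total")
  expect_error(crn_morphism(am, am,
                            species = c(x_0 = "nope", x_1 = "x_1",
                                        x_2 = "x_2"),
                            reactions = 1:4), "outside")
  expect_error(crn_morphism(am, am,
                            species = setNames(am$species, am$species),
                            reactions = c(1L, 2L, 3L, 9L)), "range")
})

test_that("reactant morphism condition holds and fails where it should", {
  m <- mi_to_am()
  expect_true(is_reactant_morphism(m)$holds)
  # identity morphism
  am <- am_net()
  idm <- crn_morphism(am, am, species = setNames(am$species, am$species),
                      reactions = 1:4)
  expect_true(is_reactant_morphism(idm)$holds)
  expect_true(is_homomorphism(idm)$holds)
  expect_true(is_stoichiomorphism(idm)$holds)
  # source reactant s0 maps to a target reaction with reactant 2*s0_hat:
  # reactant complexes do not correspond
  src <- crn(list(reaction("s0", "s1", 1)))
  tgt <- crn(list(reaction("2s0h", "s1h", 1)))
  bad <- crn_morphism(src, tgt, species = c(s0 = "s0h", s1 = "s1h"),
                      reactions = 1L)
  chk <- is_reactant_morphism(bad)
  expect_false(chk$holds)
  expect_true(nrow(chk$witnesses) >= 1)
})

test_that("homomorphism check separates the counterexample classes", {
  expect_true(is_homomorphism(mi_to_am())$holds)
  f6f <- builtin_fixture("fig6f")$network
  expect_false(is_homomorphism(f6f)$holds)
  expect_true(is_reactant_morphism(f6f)$holds)
  expect_true(is_stoichiomorphism(f6f)$holds)
  # rates traded against stoichiometry: the fiber sum matches 2k exactly
  chk <- is_stoichiomorphism(f6f)
  expect_equal(chk$max_residual, 0)
})

test_that("homomorphisms preserve stoichiometry over species fibers", {
  species_fiber_identity <- function(m) {
    phi_s <- stoich_matrices(m$source)$instantaneous
    phi_t <- stoich_matrices(m$target)$instantaneous
    mS <- matrix(0, n_species(m$source), n_species(m$target),
                 dimnames = list(m$source$species, m$target$species))
    mS[cbind(names(m$species_map), unname(m$species_map))] <- 1
    mR <- matrix(0, n_reactions(m$source), n_reactions(m$target))
    mR[cbind(seq_along(m$reaction_map), m$reaction_map)] <- 1
    max(abs(t(mS) %*% phi_s - phi_t %*% t(mR)))
  }
  for (nm in c("mi_to_am_morphism", "fig6a", "fig6b", "fig6d")) {
    m <- builtin_fixture(nm)$network
    if (is_homomorphism(m)$holds)
      expect_equal(species_fiber_identity(m), 0)
  }
  # the converse fails: m(s0 -> s0 + s1) = 2s0 -> 2s0 + s1 satisfies the
  # species-fiber identity without being a homomorphism
  src <- crn(list(reaction("s0", "s0 + s1", 1)))
  tgt <- crn(list(reaction("2s0h", "2s0h + s1h", 1)))
  m <- crn_morphism(src, tgt, species = c(s0 = "s0h", s1 = "s1h"),
                    reactions = 1L)
  expect_equal(species_fiber_identity(m), 0)
  expect_false(is_homomorphism(m)$holds)
})

test_that("stoichiomorphism failures carry the caption witnesses", {
  f6b <- builtin_fixture("fig6b")$network
  expect_true(is_homomorphism(f6b)$holds)
  chk <- is_stoichiomorphism(f6b)
  expect_false(chk$holds)
  w <- chk$witnesses[chk$witnesses$source_species == "s0", ]
  expect_equal(w$lhs, -2)
  expect_equal(w$rhs, -1)

  f6d <- builtin_fixture("fig6d")$network
  expect_true(is_homomorphism(f6d)$holds)
  chk <- is_stoichiomorphism(f6d)
  expect_false(chk$holds)
  w <- chk$witnesses[chk$witnesses$source_species == "s1", ]
  expect_equal(w$lhs, 1)
  expect_equal(w$rhs, 2)

  # disjoint copies map onto one copy as homomorphism + stoichiomorphism
  f6a <- builtin_fixture("fig6a")$network
  expect_true(is_homomorphism(f6a)$holds)
  expect_true(is_stoichiomorphism(f6a)$holds)
  expect_true(is_reactant_morphism(f6a)$holds)
})

test_that("net stoichiomorphism equals the rate-weighted check at unit rates", {
  m <- mi_to_am()
  expect_true(is_net_stoichiomorphism(m)$holds)
  expect_identical(is_net_stoichiomorphism(m)$holds,
                   is_stoichiomorphism(m)$holds)
  f6b <- builtin_fixture("fig6b")$network
  expect_false(is_net_stoichiomorphism(f6b)$holds)
  w <- is_net_stoichiomorphism(f6b)$witnesses
  expect_equal(w$lhs[w$source_species == "s0"], -2)
  # unit-rate isomorphism: entrywise eta preservation
  am <- am_net()
  perm <- crn_morphism(am, am,
                       species = c(x_0 = "x_2", x_1 = "x_1", x_2 = "x_0"),
                       reactions = c(2L, 1L, 4L, 3L))
  expect_true(is_net_stoichiomorphism(perm)$holds)
  expect_true(is_homomorphism(perm)$holds)
})

test_that("morphism properties compose", {
  m1 <- double_mi()
  m2 <- mi_to_am()
  expect_true(is_homomorphism(m1)$holds)
  expect_true(is_stoichiomorphism(m1)$holds)
  comp <- compose_morphisms(m1, m2)
  expect_true(is_reactant_morphism(comp)$holds)
  expect_true(is_stoichiomorphism(comp)$holds)
  expect_true(is_homomorphism(comp)$holds)
  # characteristic matrix of the composite is the matrix product
  cm <- function(m) {
    mm <- matrix(0, n_species(m$source), n_species(m$target),
                 dimnames = list(m$source$species, m$target$species))
    mm[cbind(names(m$species_map), unname(m$species_map))] <- 1
    mm
  }
  expect_equal(cm(comp), cm(m1) %*% cm(m2))
  # identity is neutral
  am <- am_net()
  idm <- crn_morphism(am, am, species = setNames(am$species, am$species),
                      reactions = 1:4)
  expect_identical(compose_morphisms(m2, idm)$species_map, m2$species_map)
  expect_error(compose_morphisms(m2, m1), "different networks")
})

test_that("change of rates rescales source rates by k * k_hat' / k_hat", {
  src <- crn(list(reaction("a + b", "2a", 3)))
  tgt <- crn(list(reaction("ah + bh", "2ah", 2)))
  m <- crn_morphism(src, tgt, species = c(a = "ah", b = "bh"),
                    reactions = 1L)
  lifted <- change_of_rates_lift(m, 4)
  expect_equal(lifted$source$reactions[[1]]$rate, 6)  # 3 * 4 / 2
  expect_equal(lifted$target$reactions[[1]]$rate, 4)
  expect_error(change_of_rates_lift(m, c(1, 2)), "per target reaction")
  expect_error(change_of_rates_lift(m, -1), "positive")
})

test_that("homomorphism lifts copy the target rates; lifting is invertible", {
  m <- mi_to_am()
  old_src <- rates_of(m$source)
  new_rates <- c(0.4, 1.7, 2.2, 0.9)
  lifted <- change_of_rates_lift(m, new_rates)
  # homomorphism case: source rates are exact copies through the map
  expect_identical(rates_of(lifted$source),
                   new_rates[lifted$reaction_map])
  expect_true(is_stoichiomorphism(lifted)$holds)
  expect_true(is_homomorphism(lifted)$holds)
  # identity rate change leaves the source untouched
  same <- change_of_rates_lift(m, rates_of(m$target))
  expect_identical(rates_of(same$source), old_src)
  # lifting back with the original rates restores the source exactly
  back <- change_of_rates_lift(lifted, rates_of(m$target))
  expect_identical(rates_of(back$source), old_src)
})

test_that("checks never mutate their inputs", {
  m <- mi_to_am()
  before <- c(write_crn(m$source), write_crn(m$target))
  invisible(is_reactant_morphism(m))
  invisible(is_homomorphism(m))
  invisible(is_stoichiomorphism(m))
  invisible(is_net_stoichiomorphism(m))
  after <- c(write_crn(m$source), write_crn(m$target))
  expect_identical(before, after)
})

test_that("morphism JSON round-trips through the reader", {
  m <- mi_to_am()
  js <- jsonlite::toJSON(list(
    species = as.list(m$species_map),
    reactions = lapply(seq_along(m$reaction_map), function(j)
      c(j - 1L, m$reaction_map[j] - 1L))), auto_unbox = TRUE)
  m2 <- read_morphism_json(js, m$source, m$target)
  expect_identical(m2$species_map, m$species_map)
  expect_identical(m2$reaction_map, m$reaction_map)
  js_h <- jsonlite::toJSON(list(species = as.list(m$species_map),
                                homomorphic = TRUE), auto_unbox = TRUE)
  m3 <- read_morphism_json(js_h, m$source, m$target)
  expect_identical(m3$reaction_map, m$reaction_map)
})
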