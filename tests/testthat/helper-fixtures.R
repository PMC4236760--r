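# Shared fixtures, rebuilt in code at test time.

am_net <- function() builtin_fixture("am")$network
mi_net <- function() builtin_fixture("mi")$crn
mi_influence <- function() builtin_fixture("mi")$network
mi_to_am <- function() builtin_fixture("mi_to_am_morphism")$network

rates_of <- function(net) vapply(net$reactions, `[[`, numeric(1), "rate")

# two disjoint copies of MI (nodes u,v mirror y,z), with the componentwise
# morphism onto MI
double_mi <- function() {
  inet <- influence_network(
    nodes = c("y", "z", "u", "v"),
    edges = data.frame(
      from = c("y", "y", "z", "z", "u", "u", "v", "v"),
      polarity = "high",
      to = c("y", "z", "z", "y", "u", "v", "v", "u"),
      mode = rep(c("activate", "inhibit", "activate", "inhibit"), 2),
      stringsAsFactors = FALSE))
  src <- compile_influence(inet)
  sp <- c(y_0 = "y_0", y_1 = "y_1", y_2 = "y_2",
          z_0 = "z_0", z_1 = "z_1", z_2 = "z_2",
          u_0 = "y_0", u_1 = "y_1", u_2 = "y_2",
          v_0 = "z_0", v_1 = "z_1", v_2 = "z_2")
  crn_morphism(src, mi_net(), species = sp, homomorphic = TRUE)
}

# named target states drawn reproducibly, with some boundary states mixed in
sample_states <- function(net, n, seed0 = 1000, zero_every = 5L) {
  lapply(seq_len(n), function(i)
    random_state(seed0 + i, net,
                 zero_prob = if (i %% zero_every == 0L) 0.4 else 0))
}
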