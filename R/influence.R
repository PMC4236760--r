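## Influence networks (activation/inhibition graphs) and their compilation
## to chemical reaction networks via the triplet motif: each node x becomes
## three species x_0 (active), x_1 (intermediary), x_2 (inactive) with four
## catalyzed transitions per activator/inhibitor pair.  Also the motif's
## steady-state closed form and its generalized Hill characterization.

#' Construct an influence network
#'
#' Nodes range between an active and an inactive state; edges catalytically
#' push their target towards activation or inhibition.  An edge runs from a
#' source node's high output (the node's active species) or low output (its
#' inactive species) to a target node, in `activate` or `inhibit` mode, and
#' carries one rate per catalyzed transition.  At most one edge of each
#' (source, polarity, target, mode) kind may connect a pair of (possibly
#' coincident) nodes.
#'
#' @param nodes character vector of node tokens.
#' @param edges a data frame (or list of lists coercible to one) with
#'   columns `from`, `polarity` (`"high"` or `"low"`), `to`, `mode`
#'   (`"activate"` or `"inhibit"`), and optionally `rate1`, `rate2`
#'   (default 1): the rates of the two catalyzed transitions, in the order
#'   given under [compile_influence()].
#' @return an object of class `influence_network`.
#' @examples
#' mi <- influence_network(
#'   nodes = c("y", "z"),
#'   edges = data.frame(
#'     from = c("y", "y", "z", "z"), polarity = "high",
#'     to   = c("y", "z", "z", "y"),
#'     mode = c("activate", "inhibit", "activate", "inhibit")))
#' @export
influence_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  bad <- nodes[!is_species_token(nodes)]
  if (length(bad))
    stop("invalid node token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(nodes)) stop("duplicated nodes", call. = FALSE)
  if (is.null(edges))
    edges <- data.frame(from = character(0), polarity = character(0),
                        to = character(0), mode = character(0),
                        rate1 = numeric(0), rate2 = numeric(0),
                        stringsAsFactors = FALSE)
  if (!is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, as.data.frame))
  if (is.null(edges$rate1)) edges$rate1 <- 1
  if (is.null(edges$rate2)) edges$rate2 <- 1
  edges <- edges[, c("from", "polarity", "to", "mode", "rate1", "rate2")]
  for (col in c("from", "polarity", "to", "mode"))
    edges[[col]] <- as.character(edges[[col]])
  dangling <- setdiff(c(edges$from, edges$to), nodes)
  if (length(dangling))
    stop("edge endpoint(s) not in the node list: ",
         paste(unique(dangling), collapse = ", "), call. = FALSE)
  if (!all(edges$polarity %in% c("high", "low")))
    stop("polarity must be 'high' or 'low'", call. = FALSE)
  if (!all(edges$mode %in% c("activate", "inhibit")))
    stop("mode must be 'activate' or 'inhibit'", call. = FALSE)
  if (any(edges$rate1 <= 0) || any(edges$rate2 <= 0))
    stop("edge rates must be strictly positive", call. = FALSE)
  key <- with(edges, paste(from, polarity, to, mode))
  if (anyDuplicated(key))
    stop("at most one edge of each (source, polarity, target, mode) kind ",
         "is allowed; duplicated: ", key[duplicated(key)][1], call. = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "influence_network")
}

#' @export
print.influence_network <- function(x, ...) {
  cat("Influence network: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  cat("nodes:", paste(x$nodes, collapse = " "), "\n")
  if (nrow(x$edges))
    for (i in seq_len(nrow(x$edges)))
      with(x$edges[i, ], cat("  ", from, " (", polarity, ") --", mode,
                             "--> ", to, "  [", rate1, ", ", rate2, "]\n",
                             sep = ""))
  invisible(x)
}

triplet_species <- function(node) paste0(node, "_", 0:2)

#' Compile an influence network to a chemical reaction network
#'
#' Every node `n` becomes the species `n_0` (active), `n_1` (intermediary)
#' and `n_2` (inactive); `n_1` never occurs outside the node's own
#' transitions.  Every edge contributes two catalytic reactions, with
#' catalyst `c` the source node's active species (`_0`) for a high-output
#' edge or its inactive species (`_2`) for a low-output edge:
#'
#' * activate: `c + n_1 ->{rate1} c + n_0` and `c + n_2 ->{rate2} c + n_1`
#' * inhibit:  `c + n_0 ->{rate1} c + n_1` and `c + n_1 ->{rate2} c + n_2`
#'
#' Duplicate reactions arising from distinct edges are merged by rate
#' summation as in [crn()].  The triplet bindings are attached as the
#' `"triplets"` attribute (see [triplet_bindings()]).
#'
#' @param inet an [influence_network()].
#' @return a [crn()] with `3 * length(nodes)` species.
#' @export
compile_influence <- function(inet) {
  stopifnot(inherits(inet, "influence_network"))
  species <- unlist(lapply(inet$nodes, triplet_species))
  reactions <- list()
  for (i in seq_len(nrow(inet$edges))) {
    e <- inet$edges[i, ]
    cat_sp <- paste0(e$from, "_", if (e$polarity == "high") 0 else 2)
    n <- triplet_species(e$to)    # n_0, n_1, n_2
    cx <- function(a, b) as_complex(stats::setNames(
      if (a == b) 2L else c(1L, 1L), unique(c(a, b))))
    if (e$mode == "activate") {
      r1 <- reaction(cx(cat_sp, n[2]), cx(cat_sp, n[1]), e$rate1)
      r2 <- reaction(cx(cat_sp, n[3]), cx(cat_sp, n[2]), e$rate2)
    } else {
      r1 <- reaction(cx(cat_sp, n[1]), cx(cat_sp, n[2]), e$rate1)
      r2 <- reaction(cx(cat_sp, n[2]), cx(cat_sp, n[3]), e$rate2)
    }
    reactions <- c(reactions, list(r1, r2))
  }
  net <- crn(reactions, species = species)
  bindings <- data.frame(node = inet$nodes,
                         s0 = paste0(inet$nodes, "_0"),
                         s1 = paste0(inet$nodes, "_1"),
                         s2 = paste0(inet$nodes, "_2"),
                         stringsAsFactors = FALSE)
  attr(net, "triplets") <- bindings
  net
}

#' Triplet bindings of a compiled influence network
#'
#' @param net a network produced by [compile_influence()].
#' @return a data frame with columns `node`, `s0`, `s1`, `s2`.
#' @export
triplet_bindings <- function(net) {
  b <- attr(net, "triplets")
  if (is.null(b))
    stop("network carries no triplet bindings (not produced by ",
         "compile_influence)", call. = FALSE)
  b
}

#' Replace a node by its dual
#'
#' The dual `~x` of a node renames its active and inactive species
#' (`~x_0 = x_2`, `~x_1 = x_1`, `~x_2 = x_0`) without changing the
#' underlying reaction network.  On the influence-network side this swaps
#' the polarity of the node's outgoing edges and, on its incoming edges,
#' swaps activate with inhibit while exchanging the two transition rates.
#' Dualizing twice restores the original network.
#'
#' @param inet an [influence_network()].
#' @param node the node token to dualize.
#' @return the dualized `influence_network`.
#' @export
dualize <- function(inet, node) {
  stopifnot(inherits(inet, "influence_network"))
  if (!node %in% inet$nodes)
    stop("unknown node: ", node, call. = FALSE)
  e <- inet$edges
  out <- e$from == node
  e$polarity[out] <- ifelse(e$polarity[out] == "high", "low", "high")
  inc <- e$to == node
  e$mode[inc] <- ifelse(e$mode[inc] == "activate", "inhibit", "activate")
  tmp <- e$rate1[inc]; e$rate1[inc] <- e$rate2[inc]; e$rate2[inc] <- tmp
  influence_network(inet$nodes, e)
}

#' Steady state of the triplet motif under clamped inputs
#'
#' For a single node driven by a clamped activator concentration `a`
#' (catalyzing `x_1 -> x_0` at `ka1` and `x_2 -> x_1` at `ka2`) and a
#' clamped inhibitor concentration `b` (catalyzing `x_0 -> x_1` at `kb1`
#' and `x_1 -> x_2` at `kb2`), mass action flux balance gives the unique
#' interior fixed point with `x0 + x1 + x2 = total` in the proportions
#' `x0 : x1 : x2 = (ka1 a)/(kb1 b) : 1 : (kb2 b)/(ka2 a)`.  With all rates
#' equal this yields the activated fraction `x0/total =
#' a^2 / (a^2 + a b + b^2)`, a generalized Hill response of coefficient 2.
#'
#' @param rates positive numeric vector `c(ka1, ka2, kb1, kb2)`.
#' @param a,b clamped activator and inhibitor concentrations.  If one of
#'   them is zero the boundary fixed point is returned (all mass in `x0`
#'   when `b = 0`, all in `x2` when `a = 0`) with attribute
#'   `boundary = TRUE`.
#' @param total total triplet concentration `x0 + x1 + x2`.
#' @return named numeric vector `c(x0, x1, x2)`.
#' @export
triplet_steady_state <- function(rates, a, b, total = 1) {
  rates <- as.numeric(rates)
  stopifnot(length(rates) == 4L, all(rates > 0), total > 0,
            a >= 0, b >= 0)
  if (a == 0 && b == 0)
    stop("at least one of a, b must be positive", call. = FALSE)
  if (a == 0)
    return(structure(c(x0 = 0, x1 = 0, x2 = total), boundary = TRUE))
  if (b == 0)
    return(structure(c(x0 = total, x1 = 0, x2 = 0), boundary = TRUE))
  ka1 <- rates[1]; ka2 <- rates[2]; kb1 <- rates[3]; kb2 <- rates[4]
  c0 <- (ka1 * a) / (kb1 * b)
  c2 <- (kb2 * b) / (ka2 * a)
  x1 <- total / (c0 + 1 + c2)
  structure(c(x0 = c0 * x1, x1 = x1, x2 = c2 * x1), boundary = FALSE)
}

#' Reaction network of the clamped triplet motif
#'
#' Builds the five-species catalytic network behind
#' [triplet_steady_state()]: the triplet `x_0, x_1, x_2` plus explicit
#' catalyst species `a` and `b`.  Catalysts appear with equal multiplicity
#' on both sides of every reaction, so their derivatives vanish and they
#' behave as clamped inputs under simulation.
#'
#' @param rates positive numeric vector `c(ka1, ka2, kb1, kb2)`.
#' @param node,activator,inhibitor species name stems.
#' @return a [crn()].
#' @export
triplet_crn <- function(rates = c(1, 1, 1, 1), node = "x",
                        activator = "a", inhibitor = "b") {
  rates <- as.numeric(rates)
  stopifnot(length(rates) == 4L, all(rates > 0))
  x <- triplet_species(node)
  crn(list(
    reaction(paste(activator, "+", x[2]), paste(activator, "+", x[1]),
             rates[1]),
    reaction(paste(activator, "+", x[3]), paste(activator, "+", x[2]),
             rates[2]),
    reaction(paste(inhibitor, "+", x[1]), paste(inhibitor, "+", x[2]),
             rates[3]),
    reaction(paste(inhibitor, "+", x[2]), paste(inhibitor, "+", x[3]),
             rates[4])),
    species = c(activator, inhibitor, x))
}

#' Limiting Hill coefficient of the triplet response
#'
#' Evaluates the steady-state activated fraction `x0/total` of the triplet
#' motif across a logarithmic grid of input ratios `r = a/b` and estimates
#' the limiting log-log slope of the response as `r -> 0` by least squares
#' over the smallest two decades of the grid.  For equal rates the
#' response is `r^2 / (r^2 + r + 1)` and the limiting slope is 2: the
#' motif's generalized Hill coefficient.
#'
#' @param rates positive numeric vector `c(ka1, ka2, kb1, kb2)`.
#' @param ratio_grid positive input ratios spanning at least 4 decades
#'   around 1.
#' @return the fitted exponent, with the grid responses attached as the
#'   `"response"` attribute.
#' @export
hill_coefficient <- function(rates = c(1, 1, 1, 1),
                             ratio_grid = 10^seq(-4, 4, by = 0.25)) {
  ratio_grid <- sort(as.numeric(ratio_grid))
  if (length(ratio_grid) < 5L || any(ratio_grid <= 0) ||
      max(ratio_grid) / min(ratio_grid) < 1e4 ||
      min(ratio_grid) >= 1 || max(ratio_grid) <= 1)
    stop("ratio_grid must be positive and span at least 4 decades ",
         "around 1", call. = FALSE)
  frac <- vapply(ratio_grid, function(r)
    triplet_steady_state(rates, a = r, b = 1, total = 1)[["x0"]],
    numeric(1))
  sel <- ratio_grid <= min(ratio_grid) * 100   # smallest two decades
  if (sum(sel) < 2L)
    stop("degenerate grid: need at least two points in the smallest two ",
         "decades", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, log(ratio_grid[sel])), log(frac[sel]))
  structure(unname(fit$coefficients[2]),
            response = data.frame(ratio = ratio_grid, x0_fraction = frac))
}
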