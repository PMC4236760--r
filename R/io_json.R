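## JSON interchange: influence networks, morphism maps, states and rate
## assignments.

#' Read and write influence networks as JSON
#'
#' Schema: `{"nodes": ["y", ...], "edges": [{"from": "y", "polarity":
#' "high", "to": "z", "mode": "inhibit", "rates": [1, 1]}, ...]}`; the
#' two-element `rates` array holds the two transition rates (default 1).
#'
#' @param path file path (or, for `parse_influence_json`, a JSON string).
#' @param inet an [influence_network()].
#' @return an `influence_network` (readers) or the path (writer).
#' @export
read_influence_json <- function(path) {
  parse_influence_json(paste(readLines(path, warn = FALSE),
                             collapse = "\n"))
}

#' @rdname read_influence_json
#' @export
parse_influence_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  edges <- do.call(rbind, lapply(x$edges, function(e) {
    rates <- if (is.null(e$rates)) c(1, 1) else as.numeric(e$rates)
    if (length(rates) == 1L) rates <- rep(rates, 2)
    data.frame(from = e$from,
               polarity = if (is.null(e$polarity)) "high" else e$polarity,
               to = e$to, mode = e$mode,
               rate1 = rates[1], rate2 = rates[2],
               stringsAsFactors = FALSE)
  }))
  influence_network(unlist(x$nodes), edges)
}

#' @rdname read_influence_json
#' @export
write_influence_json <- function(inet, path) {
  stopifnot(inherits(inet, "influence_network"))
  edges <- lapply(seq_len(nrow(inet$edges)), function(i) {
    e <- inet$edges[i, ]
    list(from = e$from, polarity = e$polarity, to = e$to, mode = e$mode,
         rates = c(e$rate1, e$rate2))
  })
  jsonlite::write_json(list(nodes = inet$nodes, edges = edges), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a morphism map from JSON
#'
#' Schema: `{"species": {"y_0": "x_0", ...}, "reactions": [[0, 0],
#' [1, 1], ...]}` with 0-based `[source, target]` reaction index pairs, or
#' `{"species": {...}, "homomorphic": true}` to derive the reaction map
#' from the species map.
#'
#' @param path file path or JSON string.
#' @param source,target the networks the map runs between.
#' @return a [crn_morphism()].
#' @export
read_morphism_json <- function(path, source, target) {
  txt <- if (file.exists(path))
    paste(readLines(path, warn = FALSE), collapse = "\n") else path
  x <- jsonlite::fromJSON(txt)
  species <- unlist(x$species)
  if (isTRUE(x$homomorphic))
    return(crn_morphism(source, target, species = species,
                        homomorphic = TRUE))
  pairs <- x$reactions
  if (is.null(pairs))
    stop("morphism JSON needs either \"reactions\" pairs or ",
         "\"homomorphic\": true", call. = FALSE)
  pairs <- if (is.matrix(pairs)) matrix(as.integer(pairs), ncol = 2)
           else matrix(as.integer(unlist(pairs)), ncol = 2, byrow = TRUE)
  reactions <- integer(n_reactions(source))
  reactions[pairs[, 1] + 1L] <- pairs[, 2] + 1L
  if (any(reactions == 0L))
    stop("morphism JSON reaction map is not total", call. = FALSE)
  crn_morphism(source, target, species = species, reactions = reactions)
}

#' Read a state (or rate assignment) from JSON
#'
#' A flat object `{"x_0": 1.5, ...}` mapping names to numbers.
#'
#' @param path file path or JSON string.
#' @return named numeric vector.
#' @export
read_named_numbers_json <- function(path) {
  txt <- if (file.exists(path))
    paste(readLines(path, warn = FALSE), collapse = "\n") else path
  unlist(jsonlite::fromJSON(txt))
}
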