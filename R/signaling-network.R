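# Signed directed-graph model of the MLCK/MLCP signalling cascade.
#
# Nodes are the cascade's effectors; each directed edge carries a sign (+1
# activation, -1 inhibition). A reagent perturbation binds to one node with a
# mode (activate/inhibit); its predicted effect on MLC phosphorylation (the
# sink node "pMLC") is the mode sign times the product of edge signs along
# each simple path to the sink. Prediction is static sign propagation -- no
# kinetics are simulated.

#' Default MLCK/MLCP cascade network
#'
#' Builds the signalling cascade as an [igraph::igraph] with an edge
#' attribute `sign`. Kinase arm: Ras -> RAF-1 -> MEK -> ERK -> MLCK and the
#' calcium-calmodulin complex -> MLCK, with MLCK -> pMLC (+). Phosphatase
#' arm: MLCP -> pMLC (-), inhibited by CPI-17 (activated by PKC) and by ROCK
#' (activated by RhoA, itself activated by RAF-1, calcium and TNF-alpha). PKC
#' is activated by PLC and inhibited by PKG; PKG is activated by nitric oxide
#' and reduced through the prostacyclin arm (PGI2 -> cAMP -> PKA -> PDE5),
#' with PDE5 -| PKG because PDE5 degrades the cGMP that sustains PKG. PKC
#' feeds forward to ERK.
#'
#' @return An igraph object of class `signed_network` with vertex names and a
#'   numeric `sign` edge attribute in `{-1, +1}`.
#' @export
build_default_network <- function() {
  edges <- default_edge_list()
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  class(g) <- c("signed_network", class(g))
  g
}

#' Edge list of the default cascade
#'
#' @return Data frame with columns `source`, `target`, `sign`.
#' @export
default_edge_list <- function() {
  e <- rbind(
    c("MLCK",           "pMLC",   +1),
    c("MLCP",           "pMLC",   -1),
    c("Ca-calmodulin",  "MLCK",   +1),
    c("ERK",            "MLCK",   +1),
    c("MEK",            "ERK",    +1),
    c("RAF-1",          "MEK",    +1),
    c("Ras",            "RAF-1",  +1),
    c("PKC",            "ERK",    +1),
    c("PKC",            "CPI-17", +1),
    c("CPI-17",         "MLCP",   -1),
    c("PLC",            "PKC",    +1),
    c("PKG",            "PKC",    -1),
    c("NO",             "PKG",    +1),
    c("PDE5",           "PKG",    -1),
    c("PGI2",           "cAMP",   +1),
    c("cAMP",           "PKA",    +1),
    c("PKA",            "PDE5",   +1),
    c("ROCK",           "MLCP",   -1),
    c("RhoA",           "ROCK",   +1),
    c("RAF-1",          "RhoA",   +1),
    c("Ca-calmodulin",  "RhoA",   +1),
    c("TNFa",           "RhoA",   +1))
  data.frame(source = e[, 1L], target = e[, 2L],
             sign = as.numeric(e[, 3L]), stringsAsFactors = FALSE)
}

#' Reagent perturbation of one cascade node
#'
#' @param reagent Reagent label.
#' @param target_node Node the reagent binds.
#' @param mode `"inhibit"` or `"activate"`.
#' @return An object of class `perturbation`.
#' @examples
#' perturbation("ML7", "MLCK", "inhibit")
#' @export
perturbation <- function(reagent, target_node, mode = c("inhibit", "activate")) {
  mode <- match.arg(mode)
  structure(list(reagent = reagent, target_node = target_node, mode = mode,
                 mode_sign = if (mode == "inhibit") -1 else +1),
            class = "perturbation")
}

#' Default reagent-to-target bindings
#'
#' The eight reagents used to probe the cascade: both PDE5 inhibitors
#' (sildenafil, Cpd7a), the ERK-arm activator U46619 (thromboxane analogue),
#' the direct PKC activator PMA and PKC inhibitor K252d, the MLCP inhibitor
#' okadaic acid, the MLCK inhibitor ML7, and the ROCK inhibitor Y27632.
#'
#' @return Named list of [perturbation()] objects.
#' @export
default_perturbations <- function() {
  p <- list(
    perturbation("U46619",       "ERK",  "activate"),
    perturbation("PMA",          "PKC",  "activate"),
    perturbation("okadaic_acid", "MLCP", "inhibit"),
    perturbation("sildenafil",   "PDE5", "inhibit"),
    perturbation("Cpd7a",        "PDE5", "inhibit"),
    perturbation("ML7",          "MLCK", "inhibit"),
    perturbation("K252d",        "PKC",  "inhibit"),
    perturbation("Y27632",       "ROCK", "inhibit"))
  stats::setNames(p, vapply(p, `[[`, character(1), "reagent"))
}

#' Observed direction of force/pMLC change per reagent
#'
#' Directions measured by the contraction and ELISA assays: the four
#' activators (and, paradoxically, the PDE5 inhibitor sildenafil) raised
#' force and pMLC; the four inhibitors lowered both.
#'
#' @return Named character vector with values `"up"`/`"down"`.
#' @export
default_observed_directions <- function() {
  c(U46619 = "up", PMA = "up", okadaic_acid = "up", sildenafil = "up",
    Cpd7a = "down", ML7 = "down", K252d = "down", Y27632 = "down")
}

# sign products over every simple path from `from` to the sink
.path_sign_products <- function(net, from, sink = "pMLC") {
  paths <- igraph::all_simple_paths(net, from = from, to = sink, mode = "out")
  vapply(paths, function(p) {
    ep <- igraph::E(net, path = p)
    prod(igraph::edge_attr(net, "sign", ep))
  }, numeric(1))
}

#' Predicted direction of pMLC change under a perturbation
#'
#' For every simple path from the perturbed node to `pMLC`, the path effect
#' is the perturbation's mode sign times the product of edge signs. The
#' prediction is `"up"` if all path effects are positive, `"down"` if all are
#' negative, `"ambiguous"` if they disagree. Perturbing `pMLC` itself acts
#' directly (no path product).
#'
#' @param net A [build_default_network()] graph.
#' @param pert A [perturbation()].
#' @param sink Sink node name (default `"pMLC"`).
#' @return One of `"up"`, `"down"`, `"ambiguous"`.
#' @export
predict_pmlc_direction <- function(net, pert, sink = "pMLC") {
  stopifnot(inherits(pert, "perturbation"))
  if (!pert$target_node %in% igraph::V(net)$name)
    cf_stop(sprintf("node '%s' is not in the network", pert$target_node),
            "clotforce_lookup_error")
  if (pert$target_node == sink) {
    return(if (pert$mode_sign > 0) "up" else "down")
  }
  prods <- .path_sign_products(net, pert$target_node, sink)
  if (!length(prods))
    cf_stop(sprintf("no path from '%s' to '%s'", pert$target_node, sink),
            "clotforce_no_path")
  effects <- pert$mode_sign * prods
  if (all(effects > 0)) "up" else if (all(effects < 0)) "down" else "ambiguous"
}

#' Compare cascade predictions with observed directions
#'
#' Tabulates, per reagent, the sign-propagation prediction against the
#' observed direction of force/pMLC change. With the default bindings and
#' observations, 7 of 8 reagents are concordant; sildenafil is the sole
#' mismatch (predicted down as a PDE5 inhibitor, observed up).
#'
#' @param net A [build_default_network()] graph.
#' @param perturbations Named list of [perturbation()] objects (default
#'   [default_perturbations()]).
#' @param observed Named character vector of observed directions (default
#'   [default_observed_directions()]); every name must match a perturbation.
#' @return Data frame with columns `reagent`, `target`, `mode`, `predicted`,
#'   `observed`, `match`; attribute `concordance` gives the matching count.
#' @export
compare_predictions <- function(net = build_default_network(),
                                perturbations = default_perturbations(),
                                observed = default_observed_directions()) {
  if (!length(observed)) {
    out <- data.frame(reagent = character(), target = character(),
                      mode = character(), predicted = character(),
                      observed = character(), match = logical())
    attr(out, "concordance") <- 0L
    return(out)
  }
  unknown <- setdiff(names(observed), names(perturbations))
  if (length(unknown))
    cf_stop(sprintf("unknown reagent(s): %s", paste(unknown, collapse = ", ")),
            "clotforce_lookup_error")
  rows <- lapply(names(observed), function(rg) {
    pert <- perturbations[[rg]]
    pred <- predict_pmlc_direction(net, pert)
    data.frame(reagent = rg, target = pert$target_node, mode = pert$mode,
               predicted = pred, observed = unname(observed[[rg]]),
               match = pred == observed[[rg]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "concordance") <- sum(out$match)
  out
}

#' Write / read a signed network as an edge-list CSV
#'
#' @param net A signed network (igraph with `sign` edge attribute).
#' @param path CSV path (columns `source`, `target`, `sign`).
#' @return `read_network_csv` returns the reconstructed graph.
#' @export
write_network_csv <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  names(el)[1:2] <- c("source", "target")
  utils::write.csv(el[, c("source", "target", "sign")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  el <- utils::read.csv(path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = TRUE)
  class(g) <- c("signed_network", class(g))
  g
}
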