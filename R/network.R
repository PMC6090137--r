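new_fbi_network <- function(medium, direction, sources, targets, weights) {
  stopifnot(nrow(weights) == length(sources), ncol(weights) == length(targets))
  structure(
    list(medium = medium, direction = direction,
         sources = sources, targets = targets,
         weights = matrix(as.integer(weights), nrow = length(sources),
                          dimnames = list(sources, targets))),
    class = "fbi_network"
  )
}

#' @export
print.fbi_network <- function(x, ...) {
  cat(sprintf("<fbi_network> %s, %s: %d x %d, %d link(s), connectivity %.1f%%\n",
              x$medium, x$direction, length(x$sources), length(x$targets),
              sum(x$weights != 0), connectivity(x)))
  print(x$weights)
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.fbi_network <- function(x, ...) {
  tidyr::expand_grid(source = x$sources, target = x$targets) |>
    dplyr::mutate(
      medium = x$medium, direction = x$direction,
      grade = as.integer(t(x$weights))[seq_len(dplyr::n())],
      sign = sign(.data$grade)
    ) |>
    dplyr::select("source", "target", "medium", "direction", "grade", "sign")
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Assemble per-medium directed bipartite networks
#'
#' Builds, for every medium, two directed weighted networks: the effects of
#' fungi on bacterial growth and the effects of bacteria on fungal growth
#' (with the default four media, eight networks). An edge from source strain
#' `s` to target strain `t` carries the interaction grade of `s`'s effect on
#' `t` -- i.e. the grade of the comparison where `t` was the focal
#' (measured) organism and `s` the partner. Grade 0 means no link. Node
#' order follows the roster, so weight matrices serialise reproducibly.
#'
#' @param grades Grade table from [grade_interactions()]; must be complete
#'   (status `"ok"`) for every cross-kingdom pair of the roster.
#' @param strains Roster tibble; defaults to the strains present in `grades`.
#' @return Tibble with columns `medium`, `direction` and a list-column
#'   `network` of `fbi_network` objects (fields `medium`, `direction`,
#'   `sources`, `targets`, `weights`).
#' @examples
#' cfg <- fbi_sim_config(noise_cv = 0, seed = 1)
#' nets <- simulate_areas(cfg) |>
#'   compare_growth() |>
#'   grade_interactions() |>
#'   build_networks()
#' nets$network[[1]]
#' @export
build_networks <- function(grades, strains = NULL) {
  if (is.null(strains)) {
    strains <- grades |>
      dplyr::distinct(strain = .data$focal, kingdom = .data$kingdom) |>
      dplyr::arrange(dplyr::desc(.data$kingdom == "fungus"), .data$strain)
  }
  unknown <- setdiff(unique(c(grades$focal, grades$partner)), strains$strain)
  if (length(unknown)) {
    abort(paste0("Grades refer to strains outside the roster: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(grades$status != "ok")) {
    abort("Grade table has incomplete keys; resolve them before building networks.")
  }
  fungi <- strains$strain[strains$kingdom == "fungus"]
  bacteria <- strains$strain[strains$kingdom == "bacterium"]

  directions <- tibble::tibble(
    direction = c("fungi_to_bacteria", "bacteria_to_fungi"),
    source_kingdom = c("fungus", "bacterium")
  )

  out <- tidyr::expand_grid(medium = unique(grades$medium), directions)
  out$network <- purrr::pmap(out, function(medium, direction, source_kingdom) {
    sources <- if (source_kingdom == "fungus") fungi else bacteria
    targets <- if (source_kingdom == "fungus") bacteria else fungi
    sub <- grades[grades$medium == medium & grades$kingdom != source_kingdom, ]
    w <- matrix(0L, length(sources), length(targets))
    expected <- length(sources) * length(targets)
    if (nrow(sub) != expected) {
      abort(sprintf("Medium %s, %s: expected %d grades, got %d.",
                    medium, direction, expected, nrow(sub)))
    }
    # grade of source's effect on target: source = partner, target = focal
    i <- match(sub$partner, sources)
    j <- match(sub$focal, targets)
    w[cbind(i, j)] <- sub$grade
    new_fbi_network(medium, direction, sources, targets, w)
  })
  dplyr::select(out, "medium", "direction", "network")
}

#' Network connectivity
#'
#' The percentage of realised directed links out of all possible ones given
#' the node sets and directionality: `100 * nonzero / (sources x targets)`.
#' The default 4-fungi/5-bacteria roster allows 20 links per direction.
#'
#' @param net An `fbi_network`.
#' @return Connectivity in percent.
#' @export
connectivity <- function(net) {
  stopifnot(inherits(net, "fbi_network"))
  100 * sum(net$weights != 0) / length(net$weights)
}

#' Connectivity of every network in a bundle
#'
#' @param networks Network tibble from [build_networks()].
#' @return Tibble: `medium`, `direction`, `n_links`, `n_possible`,
#'   `connectivity` (percent).
#' @export
connectivity_table <- function(networks) {
  networks |>
    dplyr::mutate(
      n_links = purrr::map_int(.data$network, ~ sum(.x$weights != 0)),
      n_possible = purrr::map_int(.data$network, ~ length(.x$weights)),
      connectivity = purrr::map_dbl(.data$network, connectivity)
    ) |>
    dplyr::select(-"network")
}

#' Export and import networks
#'
#' `write_network_edges()` writes the nonzero links of one or many networks
#' as an edge-list CSV (`source, target, medium, direction, grade, sign`;
#' sign +1 = induction, -1 = repression, matching the blue/red rendering
#' convention). `read_network_edges()` rebuilds the weight matrices; because
#' the CSV stores only realised links, the node rosters must be supplied.
#' `write_network_graphml()`/`read_network_graphml()` round-trip a single
#' network through GraphML (via igraph) with all nodes preserved, node
#' attributes `kingdom_role` (source/target) and edge attributes `weight`
#' and `sign`.
#'
#' @param networks Network tibble from [build_networks()] (or a single
#'   `fbi_network` for the GraphML writer).
#' @param path Output file.
#' @param sources,targets Node rosters, in order, for rebuilding from an
#'   edge list.
#' @param net A single `fbi_network`.
#' @return Writers return the path invisibly; readers return a network
#'   tibble (`read_network_edges`) or an `fbi_network`
#'   (`read_network_graphml`).
#' @export
write_network_edges <- function(networks, path) {
  if (inherits(networks, "fbi_network")) {
    networks <- tibble::tibble(medium = networks$medium,
                               direction = networks$direction,
                               network = list(networks))
  }
  edges <- purrr::map_dfr(networks$network, as_tibble) |>
    dplyr::filter(.data$grade != 0)
  readr::write_csv(edges, path)
  invisible(path)
}

#' @rdname write_network_edges
#' @export
read_network_edges <- function(path, sources, targets) {
  edges <- readr::read_csv(path, show_col_types = FALSE)
  combos <- dplyr::distinct(edges, .data$medium, .data$direction)
  combos$network <- purrr::map2(combos$medium, combos$direction, function(m, d) {
    sub <- edges[edges$medium == m & edges$direction == d, ]
    w <- matrix(0L, length(sources), length(targets))
    i <- match(sub$source, sources)
    j <- match(sub$target, targets)
    if (anyNA(i) || anyNA(j)) abort("Edge refers to a node outside the roster.")
    w[cbind(i, j)] <- as.integer(sub$grade)
    new_fbi_network(m, d, sources, targets, w)
  })
  combos
}

#' @rdname write_network_edges
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "fbi_network"))
  edges <- as_tibble(net) |> dplyr::filter(.data$grade != 0)
  nodes <- data.frame(
    name = c(net$sources, net$targets),
    kingdom_role = rep(c("source", "target"),
                       c(length(net$sources), length(net$targets)))
  )
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$source, to = edges$target,
               weight = edges$grade, sign = edges$sign),
    directed = TRUE, vertices = nodes
  )
  g <- igraph::set_graph_attr(g, "medium", net$medium)
  g <- igraph::set_graph_attr(g, "direction", net$direction)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_edges
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  sources <- nodes[igraph::V(g)$kingdom_role == "source"]
  targets <- nodes[igraph::V(g)$kingdom_role == "target"]
  w <- matrix(0L, length(sources), length(targets))
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    w[cbind(match(el[, 1], sources), match(el[, 2], targets))] <-
      as.integer(igraph::E(g)$weight)
  }
  new_fbi_network(igraph::graph_attr(g, "medium"),
                  igraph::graph_attr(g, "direction"),
                  sources, targets, w)
}

#' Plot a bipartite interaction network
#'
#' Source strains on the top row, targets on the bottom; line colour encodes
#' the sign of the interaction (induction vs repression) and line width its
#' strength.
#'
#' @param object An `fbi_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fbi_network <- function(object, ...) {
  nodes <- dplyr::bind_rows(
    tibble::tibble(strain = object$sources, y = 1,
                   x = seq_along(object$sources)),
    tibble::tibble(strain = object$targets, y = 0,
                   x = seq_along(object$targets))
  )
  edges <- as_tibble(object) |>
    dplyr::filter(.data$grade != 0) |>
    dplyr::left_join(nodes, by = c(source = "strain")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(target = "strain")) |>
    dplyr::mutate(effect = ifelse(.data$sign > 0, "induction", "repression"))
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, colour = .data$effect,
                   linewidth = abs(.data$grade)),
      alpha = 0.8
    )
  }
  p +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 9,
                        shape = 21, fill = "grey95") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$strain),
                       size = 3) +
    ggplot2::scale_colour_manual(
      values = c(induction = "#2166ac", repression = "#b2182b")) +
    ggplot2::scale_linewidth(range = c(0.3, 2.5), limits = c(1, 6)) +
    ggplot2::labs(title = sprintf("%s (%s)", object$medium, object$direction),
                  colour = NULL, linewidth = "|grade|") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
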