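#' Geomorphic stream networks
#'
#' A geomorphic (potential) stream network is represented as a tibble of
#' nodes with class `stream_network`. Each node stands for a uniform stream
#' reach of length `reach_length` and points to the next node towards the
#' outlet via `downstream_id` (`NA` at the outlet), so the links form a
#' rooted tree. Terrain attributes carried per node are the local slope,
#' the contributing area (in unit-node equivalents) and the topographic
#' wetness index (TWI).
#'
#' Columns: `node_id`, `x`, `y`, `downstream_id`, `reach_length`, `slope`,
#' `contributing_area`, `twi`, and optionally `persistency` once a
#' persistency field has been allocated (see [allocate_persistency()]).
#'
#' @name stream_network
NULL

new_stream_network <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("stream_network", class(df))
  df
}

#' Coerce a data frame to a validated stream network
#'
#' Checks the topological invariants (unique ids, exactly one outlet, no
#' dangling downstream references, all nodes draining to the outlet without
#' cycles) and recomputes contributing area and TWI if absent.
#'
#' @param df A data frame with at least `node_id`, `downstream_id` and
#'   `reach_length` columns. `slope` is required if `twi` must be derived.
#' @return A `stream_network` tibble.
#' @export
as_stream_network <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("node_id", "downstream_id", "reach_length")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "streamdyn_format_error")
  }
  if (!all(c("x", "y") %in% names(df))) {
    df$x <- df$x %||% as.numeric(seq_len(nrow(df)))
    df$y <- df$y %||% 0
  }
  validate_network_topology(df)
  if (any(df$reach_length <= 0)) {
    rlang::abort(paste0("non-positive reach_length at row ",
                        which(df$reach_length <= 0)[1]),
                 class = "streamdyn_format_error")
  }
  needs_terrain <- !all(c("contributing_area", "twi") %in% names(df)) ||
    anyNA(df$contributing_area) || anyNA(df$twi)
  net <- new_stream_network(df)
  if (needs_terrain) net <- derive_terrain_attributes(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Topological validation: unique ids, one outlet, resolvable links, no cycles.
validate_network_topology <- function(df) {
  ids <- df$node_id
  if (anyDuplicated(ids)) {
    rlang::abort(paste0("duplicate node_id at row ", anyDuplicated(ids)),
                 class = "streamdyn_format_error")
  }
  is_outlet <- is.na(df$downstream_id)
  if (sum(is_outlet) == 0) {
    rlang::abort("no outlet: every node has a downstream link",
                 class = "streamdyn_format_error")
  }
  if (sum(is_outlet) > 1) {
    rlang::abort(paste0("multiple outlets at rows ",
                        paste(which(is_outlet), collapse = ", ")),
                 class = "streamdyn_format_error")
  }
  ds <- match(df$downstream_id, ids)
  dangling <- which(!is_outlet & is.na(ds))
  if (length(dangling) > 0) {
    rlang::abort(paste0("downstream_id references a missing node at row ",
                        dangling[1]),
                 class = "streamdyn_format_error")
  }
  # All nodes must reach the outlet; with n-1 links this also excludes cycles.
  n <- nrow(df)
  reached <- rep(FALSE, n)
  outlet <- which(is_outlet)
  reached[outlet] <- TRUE
  frontier <- outlet
  children <- split(seq_len(n), factor(ds, levels = seq_len(n)))
  while (length(frontier) > 0) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    frontier <- nxt[!reached[nxt]]
    reached[frontier] <- TRUE
  }
  if (!all(reached)) {
    rlang::abort(paste0("node(s) not draining to the outlet (cycle?) at row ",
                        which(!reached)[1]),
                 class = "streamdyn_format_error")
  }
  invisible(df)
}

# Row indices ordered from leaves towards the outlet (children before parents).
upstream_order <- function(df) {
  ds <- match(df$downstream_id, df$node_id)
  n <- nrow(df)
  depth <- rep(NA_integer_, n)
  outlet <- which(is.na(ds))
  depth[outlet] <- 0L
  children <- split(seq_len(n), factor(ds, levels = seq_len(n)))
  frontier <- outlet
  while (length(frontier) > 0) {
    nxt <- unlist(children[as.character(frontier)], use.names = FALSE)
    depth[nxt] <- depth[ds[nxt]] + 1L
    frontier <- nxt
  }
  order(depth, decreasing = TRUE)
}

#' Recompute terrain attributes of a network
#'
#' Contributing area is the number of nodes in the upstream subtree of each
#' node (itself included) times the unit node area; TWI is
#' `ln(contributing_area / slope)` with unit contour width. Both columns are
#' overwritten consistently with the current topology and slopes.
#'
#' @param network A `stream_network` (or coercible data frame).
#' @return The network with `contributing_area` and `twi` recomputed.
#' @export
derive_terrain_attributes <- function(network) {
  df <- tibble::as_tibble(network)
  validate_network_topology(df)
  if (!"slope" %in% names(df) || anyNA(df$slope)) {
    rlang::abort("slope column required to derive TWI",
                 class = "streamdyn_data_error")
  }
  if (any(df$slope <= 0)) {
    rlang::abort(paste0("non-positive slope at row ", which(df$slope <= 0)[1]),
                 class = "streamdyn_data_error")
  }
  ds <- match(df$downstream_id, df$node_id)
  area <- rep(1, nrow(df))
  for (i in upstream_order(df)) {
    if (!is.na(ds[i])) area[ds[i]] <- area[ds[i]] + area[i]
  }
  df$contributing_area <- area
  df$twi <- log(area / df$slope)
  new_stream_network(df)
}

#' Total geomorphic length of a network
#'
#' The length of the fully expanded network: the sum of all reach lengths.
#'
#' @param network A `stream_network`.
#' @return A single number, `L_g`.
#' @export
geomorphic_length <- function(network) {
  sum(network$reach_length)
}

#' Generate a synthetic stream network
#'
#' Builds a random rooted tree of `n_nodes` nodes standing in for a real
#' channel network extracted from a DEM. Reach lengths and node areas are
#' unitary (all spatial quantities in the model are relative, so only ratios
#' matter). Slopes follow a noisy slope--area scaling
#' `slope = c * A^(-0.5) * exp(eps)`, `eps ~ N(0, sigma^2)`, so that TWI is
#' correlated with, but not a deterministic function of, contributing area.
#' Coordinates are decorative (used by plots and exports only).
#'
#' @param n_nodes Number of nodes (>= 1). The bundled hydroclimatic scenarios
#'   default to 1215 nodes.
#' @param seed Integer seed; identical seeds give identical networks.
#' @param style `"random_tree"` attaches each new node to a uniformly chosen
#'   existing node; `"lattice_walk"` grows the tree on an integer lattice for
#'   a more river-like planform. Both satisfy the same contracts.
#' @param slope_coef,slope_sigma Coefficient `c` and log-normal spread
#'   `sigma` of the synthetic slope model.
#' @return A `stream_network` tibble with terrain attributes filled in.
#' @examples
#' net <- generate_network(50, seed = 1)
#' geomorphic_length(net)
#' @export
generate_network <- function(n_nodes, seed = 1L,
                             style = c("random_tree", "lattice_walk"),
                             slope_coef = 0.1, slope_sigma = 0.5) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1 || n_nodes < 1 ||
      n_nodes != round(n_nodes)) {
    rlang::abort("n_nodes must be a positive integer",
                 class = "streamdyn_argument_error")
  }
  style <- match.arg(style)
  n <- as.integer(n_nodes)
  set.seed(seed)
  parent <- rep(NA_integer_, n)
  x <- numeric(n)
  y <- numeric(n)
  if (style == "random_tree") {
    for (i in seq_len(n)[-1]) {
      p <- sample.int(i - 1L, 1L)
      parent[i] <- p
      ang <- stats::runif(1, 0, 2 * pi)
      x[i] <- x[p] + cos(ang)
      y[i] <- y[p] + sin(ang)
    }
  } else {
    occupied <- new.env(hash = TRUE, size = 2L * n)
    assign("0_0", TRUE, envir = occupied)
    steps <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
    for (i in seq_len(n)[-1]) {
      repeat {
        p <- sample.int(i - 1L, 1L)
        free <- which(vapply(seq_len(4), function(s) {
          !exists(paste0(x[p] + steps[s, 1], "_", y[p] + steps[s, 2]),
                  envir = occupied)
        }, logical(1)))
        if (length(free) > 0) break
      }
      s <- free[sample.int(length(free), 1L)]
      parent[i] <- p
      x[i] <- x[p] + steps[s, 1]
      y[i] <- y[p] + steps[s, 2]
      assign(paste0(x[i], "_", y[i]), TRUE, envir = occupied)
    }
  }
  df <- tibble::tibble(
    node_id = seq_len(n),
    x = x, y = y,
    downstream_id = parent,
    reach_length = 1,
    slope = 1  # placeholder until areas are known
  )
  ds <- parent
  area <- rep(1, n)
  for (i in upstream_order(df)) {
    if (!is.na(ds[i])) area[ds[i]] <- area[ds[i]] + area[i]
  }
  df$slope <- slope_coef * area^(-0.5) *
    exp(stats::rnorm(n, 0, slope_sigma))
  df$contributing_area <- area
  df$twi <- log(area / df$slope)
  new_stream_network(df)
}

#' Read and write node-link network tables
#'
#' The on-disk format is a CSV with header
#' `node_id,x,y,downstream_id,reach_length,slope,contributing_area,twi`;
#' `downstream_id` is empty for the outlet, and `contributing_area`/`twi`
#' are optional on input (recomputed when absent). A `persistency` column,
#' if present, is carried through. `read_network_table(write_network_table(net))`
#' reproduces the network exactly.
#'
#' @param path Path of the CSV file.
#' @param network A `stream_network`.
#' @return `read_network_table()` returns a validated `stream_network`;
#'   `write_network_table()` returns `path` invisibly.
#' @export
read_network_table <- function(path) {
  # doubles come in as text and go through strtod so the written 17
  # significant digits are recovered bit-exactly
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          node_id = readr::col_integer(),
                          downstream_id = readr::col_integer(),
                          .default = readr::col_character()
                        ))
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.character), as.numeric))
  as_stream_network(df)
}

#' @rdname read_network_table
#' @export
write_network_table <- function(network, path) {
  df <- tibble::as_tibble(network)
  # 17 significant digits so doubles survive the text round-trip exactly
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double), ~sprintf("%.17g", .x)))
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Plot a stream network
#'
#' Draws the tree as segments between each node and its downstream
#' neighbour, coloured by persistency when a field has been allocated.
#'
#' @param object A `stream_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stream_network
#' @export
autoplot.stream_network <- function(object, ...) {
  df <- tibble::as_tibble(object)
  idx <- match(df$downstream_id, df$node_id)
  seg <- df[!is.na(idx), ]
  seg$xend <- df$x[idx[!is.na(idx)]]
  seg$yend <- df$y[idx[!is.na(idx)]]
  p <- ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                         xend = .data$xend, yend = .data$yend))
  if ("persistency" %in% names(df)) {
    p <- p + ggplot2::geom_segment(ggplot2::aes(colour = .data$persistency)) +
      ggplot2::scale_colour_viridis_c(name = "persistency", limits = c(0, 1))
  } else {
    p <- p + ggplot2::geom_segment(colour = "steelblue")
  }
  p + ggplot2::coord_equal() + ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}
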