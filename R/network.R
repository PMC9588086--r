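#' A merging stream in the dilution network
#'
#' @param flow Volumetric flow rate (m^3/s) or any proportional weight,
#'   e.g. a channel width under the equal-length/height design heuristic.
#'   Must be > 0.
#' @param conc Solute concentration as a fraction of the inlet, in [0, 1].
#' @return An object of class `"stream"`.
#' @export
stream <- function(flow, conc) {
  check_scalar(flow, "flow", positive = TRUE)
  check_scalar(conc, "conc", non_negative = TRUE)
  if (conc > 1) stop("`conc` must be in [0, 1]", call. = FALSE)
  structure(list(flow = flow, conc = conc), class = "stream")
}

#' Flow-weighted concentration of merged streams
#'
#' At a channel junction the combined concentration is the flow-weighted
#' mean `sum(q_i c_i) / sum(q_i)`; total flow is conserved. With flow
#' proportional to channel width, merging 150/150 um feeds of dye and
#' buffer gives 1/2 and a 50 um dye feed against a 150 um buffer feed
#' gives 1/4 -- the device's width-tuned dilution rungs.
#'
#' @param streams List of at least two [stream()] objects.
#' @return A [stream()] with the merged flow and concentration.
#' @examples
#' merge_concentration(list(stream(150, 1), stream(150, 0)))$conc # 0.5
#' merge_concentration(list(stream(50, 1), stream(150, 0)))$conc  # 0.25
#' @export
merge_concentration <- function(streams) {
  if (!is.list(streams) || length(streams) < 2L) {
    stop("`streams` must be a list of at least two streams", call. = FALSE)
  }
  ok <- vapply(streams, inherits, logical(1), what = "stream")
  if (!all(ok)) stop("all elements must be stream objects", call. = FALSE)
  q <- vapply(streams, `[[`, numeric(1), "flow")
  ci <- vapply(streams, `[[`, numeric(1), "conc")
  stream(sum(q), sum(q * ci) / sum(q))
}

#' Hydraulic resistance of a rectangular microchannel
#'
#' Exact series solution for pressure-driven laminar flow in a rectangular
#' duct:
#' `R = 12 mu L / (w h^3) / (1 - (192 h / (pi^5 w)) * sum tanh(n pi w / (2 h)) / n^5)`
#' over odd `n`. Dimensions are swapped internally so that `w >= h`.
#' Approaches the parallel-plate value `12 mu L / (w h^3)` as `w/h` grows.
#'
#' @param width,height Channel cross-section, m.
#' @param length Channel length, m.
#' @param viscosity Dynamic viscosity, Pa s.
#' @param n_terms Number of (odd) series terms, >= 1. Default 20 is ample
#'   (the series converges as n^-5).
#' @return Hydraulic resistance, Pa s / m^3.
#' @export
rectangular_resistance <- function(width, height, length,
                                   viscosity = 1.01e-3, n_terms = 20L) {
  check_scalar(width, "width", positive = TRUE)
  check_scalar(height, "height", positive = TRUE)
  check_scalar(length, "length", positive = TRUE)
  check_scalar(viscosity, "viscosity", positive = TRUE)
  check_scalar(n_terms, "n_terms", positive = TRUE)
  w <- max(width, height)
  h <- min(width, height)
  n <- seq(1, by = 2, length.out = as.integer(n_terms))
  series <- sum(tanh(n * pi * w / (2 * h)) / n^5)
  denom <- 1 - (192 * h / (pi^5 * w)) * series
  12 * viscosity * length / (w * h^3 * denom)
}

#' Predicted output fractions of a staged dilution network
#'
#' Evaluates a tree of flow-weighted merges ([merge_concentration()]) from
#' inlet concentrations to output channels. The network is a list with:
#' \describe{
#'   \item{inlets}{named list of inlet concentrations in [0, 1], each
#'     carrying unit flow unless given as `list(conc =, flow =)`.}
#'   \item{stages}{named list, in evaluation order; each stage is a list of
#'     `list(weight =, source =)` entries whose `source` names an inlet or
#'     an earlier stage. `weight` is the feed flow (or channel width).}
#'   \item{outputs}{character vector of node names to report, in order.}
#' }
#'
#' @param network Network description (see Details), e.g. from
#'   [read_network_yaml()].
#' @return Named numeric vector of output concentrations as fractions of
#'   the dye inlet.
#' @export
ladder_fractions <- function(network) {
  if (!is.list(network) ||
      !all(c("inlets", "stages", "outputs") %in% names(network))) {
    stop("`network` must have elements inlets, stages, outputs", call. = FALSE)
  }
  nodes <- list()
  for (nm in names(network$inlets)) {
    inl <- network$inlets[[nm]]
    if (is.list(inl)) {
      nodes[[nm]] <- stream(inl$flow, inl$conc)
    } else {
      nodes[[nm]] <- stream(1, inl)
    }
  }
  for (nm in names(network$stages)) {
    feeds <- network$stages[[nm]]
    streams <- lapply(feeds, function(f) {
      if (is.null(f$source) || is.null(f$weight)) {
        stop(sprintf("stage '%s': each feed needs `weight` and `source`", nm),
             call. = FALSE)
      }
      src <- nodes[[f$source]]
      if (is.null(src)) {
        stop(sprintf("stage '%s' references unknown source '%s'",
                     nm, f$source), call. = FALSE)
      }
      stream(f$weight, src$conc)
    })
    nodes[[nm]] <- merge_concentration(streams)
  }
  missing <- setdiff(network$outputs, names(nodes))
  if (length(missing)) {
    stop(sprintf("unknown output node(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  vapply(stats::setNames(network$outputs, network$outputs),
         function(nm) nodes[[nm]]$conc, numeric(1))
}

#' The width-tuned two-stage gradient-generator network
#'
#' The reconstructed merge topology of the device's tree-like gradient
#' generator: output A passes the dye inlet through, B merges equal
#' 150/150 um dye and buffer feeds (1/2), C merges a 50 um dye feed with a
#' 150 um buffer feed (1/4), and D passes the buffer inlet through,
#' producing the 1 : 1/2 : 1/4 : 0 ladder. Flow is taken proportional to
#' feed-channel width (equal lengths and heights).
#'
#' @return A network list suitable for [ladder_fractions()].
#' @export
width_ladder_network <- function() {
  list(
    inlets = list(dye = 1.0, buffer = 0.0),
    stages = list(
      B = list(list(weight = 150, source = "dye"),
               list(weight = 150, source = "buffer")),
      C = list(list(weight = 50, source = "dye"),
               list(weight = 150, source = "buffer"))
    ),
    outputs = c("dye", "B", "C", "buffer")
  )
}
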