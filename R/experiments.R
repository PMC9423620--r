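#' Build and validate an experiment configuration
#'
#' Describes one comparison sweep: a network source (either LFR-style
#' generator parameters with a replicate count, or paths to a graph and a
#' partition file), the centrality measures to rank with, the grid of seeding
#' fractions, and the SIR settings. Validation is fail-fast: an unknown
#' measure or an out-of-range fraction errors here, before any simulation.
#'
#' @param network Either `list(type = "lfr", mu = ..., ...)` with arguments
#'   for [generate_lfr()], or `list(type = "files", graph = path,
#'   partition = path, format = "edgelist"|"gml")`.
#' @param measures Character vector of centrality ids
#'   (see [centrality_measures()]).
#' @param fo_grid Numeric vector of seeding fractions in (0, 1].
#' @param replicates Number of generated network replicates (ignored for
#'   file-based networks, which have one realization).
#' @param lambda_mult Spreading-rate multiplier applied to each network's
#'   epidemic threshold.
#' @param recovery_prob Per-step recovery probability.
#' @param runs SIR runs per (scheme, fraction) cell.
#' @param master_seed Integer master seed; every cell derives its own stream.
#' @param label Network label used in the output table.
#' @param normalization Gain normalization passed to [delta_r()].
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(network, measures, fo_grid,
                              replicates = 10L, lambda_mult = 1,
                              recovery_prob = 1, runs = 500L,
                              master_seed = 1L, label = NULL,
                              normalization = c("network", "outbreak")) {
  normalization <- match.arg(normalization)
  if (!is.list(network) || is.null(network$type) ||
      !network$type %in% c("lfr", "files")) {
    stop("experiment_config: network$type must be 'lfr' or 'files'")
  }
  if (network$type == "files") {
    for (f in c(network$graph, network$partition)) {
      if (is.null(f) || !file.exists(f)) {
        stop("experiment_config: missing network file: ", f %||% "(unset)")
      }
    }
    replicates <- 1L
  }
  if (length(measures) == 0) stop("experiment_config: no measures given")
  bad <- setdiff(measures, centrality_measures())
  if (length(bad)) {
    stop("experiment_config: unknown measure '", bad[1], "'; valid ids: ",
         paste(centrality_measures(), collapse = ", "))
  }
  if (length(fo_grid) == 0 || any(!is.finite(fo_grid)) ||
      any(fo_grid <= 0) || any(fo_grid > 1)) {
    stop("experiment_config: fo_grid values must lie in (0, 1]")
  }
  structure(list(network = network,
                 measures = as.character(measures),
                 fo_grid = as.numeric(fo_grid),
                 replicates = as.integer(replicates),
                 lambda_mult = lambda_mult,
                 recovery_prob = recovery_prob,
                 runs = as.integer(runs),
                 master_seed = as.integer(master_seed),
                 label = label %||% network$type,
                 normalization = normalization),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file holds the arguments of [experiment_config()] as flat keys, with
#' `network` as a nested mapping.
#'
#' @param path Path to a YAML config file.
#' @return An `"experiment_config"` object.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' Run a ranking-scheme comparison sweep
#'
#' For every network replicate, measure and seeding fraction, computes both
#' rankings and the relative outbreak-size gain [delta_r()], then averages
#' over replicates. Centralities are computed once per network. Every cell
#' draws from an RNG stream keyed by (master seed, replicate, measure,
#' fraction), so any execution order yields identical output and two runs of
#' the same config are identical.
#'
#' @param config An [experiment_config()] object (or path to a YAML file).
#' @param progress Print one line per network replicate (default `FALSE`).
#' @return A data frame of class `"delta_r_curve"` with one row per
#'   (measure, f_o): columns `network`, `measure`, `f_o`, `delta_r`,
#'   `stderr`, `mu`, `n_communities`. The resolved settings are attached as
#'   attribute `"manifest"`.
#' @export
run_experiment <- function(config, progress = FALSE) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  cells <- list()
  mus <- numeric(config$replicates)
  ncs <- numeric(config$replicates)
  lambdas <- numeric(config$replicates)
  for (rep in seq_len(config$replicates)) {
    net <- load_network(config, rep)
    mus[rep] <- mixing_parameter(net$graph, net$partition)
    ncs[rep] <- length(net$partition$communities)
    lam <- min(1, config$lambda_mult * epidemic_threshold(net$graph))
    lambdas[rep] <- lam
    if (progress) {
      message(sprintf("[%s] replicate %d/%d: n=%d, mu=%.3f, |C|=%d",
                      config$label, rep, config$replicates,
                      igraph::vcount(net$graph), mus[rep], ncs[rep]))
    }
    for (m in config$measures) {
      scores <- compute_centrality(net$graph, m)
      for (fo in config$fo_grid) {
        dr <- tryCatch(
          delta_r(net$graph, scores, net$partition, fo, lambda = lam,
                  recovery_prob = config$recovery_prob, runs = config$runs,
                  rng_seed = derive_seed(config$master_seed, "cell", rep, m,
                                         format(fo, digits = 12)),
                  normalization = config$normalization),
          error = function(e) {
            stop("experiment cell failed at (replicate ", rep, ", ", m,
                 ", f_o = ", fo, "): ", conditionMessage(e))
          })
        cells[[length(cells) + 1]] <-
          data.frame(replicate = rep, measure = m, f_o = fo,
                     delta_r = dr$delta_r, stderr = dr$stderr,
                     stringsAsFactors = FALSE)
      }
    }
  }
  long <- do.call(rbind, cells)
  agg <- aggregate_cells(long, config)
  attr(agg, "replicate_table") <- long
  attr(agg, "manifest") <- list(
    label = config$label,
    network = config$network,
    measures = config$measures,
    fo_grid = config$fo_grid,
    replicates = config$replicates,
    lambda_mult = config$lambda_mult,
    lambda = lambdas,
    recovery_prob = config$recovery_prob,
    runs = config$runs,
    master_seed = config$master_seed,
    normalization = config$normalization,
    realized_mu = mus,
    n_communities = ncs
  )
  agg
}

load_network <- function(config, rep) {
  nw <- config$network
  if (nw$type == "lfr") {
    args <- nw[setdiff(names(nw), "type")]
    args$rng_seed <- derive_seed(config$master_seed, "network", rep)
    net <- do.call(generate_lfr, args)
    list(graph = net$graph, partition = net$partition)
  } else {
    g <- if (identical(nw$format, "gml")) read_gml(nw$graph)
         else read_edge_list(nw$graph)
    list(graph = g, partition = read_partition(nw$partition))
  }
}

aggregate_cells <- function(long, config) {
  key <- interaction(long$measure, long$f_o, drop = TRUE)
  rows <- lapply(split(long, key), function(d) {
    se <- if (nrow(d) > 1) sd(d$delta_r) / sqrt(nrow(d)) else d$stderr
    data.frame(network = config$label,
               measure = d$measure[1],
               f_o = d$f_o[1],
               delta_r = mean(d$delta_r),
               stderr = se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$measure, out$f_o), ]
  rownames(out) <- NULL
  class(out) <- c("delta_r_curve", "data.frame")
  out
}

#' Peak gain per measure of a comparison sweep
#'
#' @param curve A `"delta_r_curve"` data frame from [run_experiment()].
#' @return A data frame with one row per measure: the maximum mean gain over
#'   the fraction grid and the fraction where it is attained.
#' @export
peak_delta_r <- function(curve) {
  stopifnot(inherits(curve, "data.frame"))
  rows <- lapply(split(curve, curve$measure), function(d) {
    i <- which.max(d$delta_r)
    data.frame(measure = d$measure[1], f_o = d$f_o[i],
               peak_delta_r = d$delta_r[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a gain curve to TSV, with a JSON manifest alongside
#'
#' The manifest records every resolved setting (seeds, spreading rate,
#' realized mixing parameters, run counts) so results are traceable.
#'
#' @param curve A `"delta_r_curve"` from [run_experiment()].
#' @param path Output TSV path; the manifest goes to `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_delta_r_curve <- function(curve, path) {
  write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  man <- attr(curve, "manifest")
  if (!is.null(man)) {
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.delta_r_curve <- function(x, ...) {
  man <- attr(x, "manifest")
  if (!is.null(man)) {
    cat("gain curve: ", man$label, ", ", man$replicates, " replicate(s), ",
        man$runs, " SIR runs/cell\n", sep = "")
  }
  print(as.data.frame(x))
  invisible(x)
}

#' Plot gain curves against the seeding fraction
#'
#' One line per centrality measure; the dashed horizontal line marks zero
#' (no difference between the schemes).
#'
#' @param x A `"delta_r_curve"` data frame.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.delta_r_curve <- function(x, ...) {
  measures <- unique(x$measure)
  fo <- sort(unique(x$f_o))
  y <- sapply(measures, function(m) {
    d <- x[x$measure == m, ]
    d$delta_r[match(fo, d$f_o)]
  })
  graphics::matplot(fo, y, type = "b", pch = 19, lty = 1,
                    xlab = "fraction of initially infected nodes",
                    ylab = expression(Delta * R ~ "(%)"), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::legend("topright", legend = measures, col = seq_along(measures),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
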