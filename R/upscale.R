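#' Configuration of the histogram-based diameter upscaling
#'
#' The goal distribution is a beta distribution on `[d_min, d_max]` with
#' the given mean and standard deviation (in um). Shape parameters are
#' solved from the moments on the unit interval: with
#' `m = (mean - d_min) / (d_max - d_min)` and `v = (sd / (d_max - d_min))^2`,
#' `alpha = m * (m (1 - m) / v - 1)` and `beta = (1 - m) * (m (1 - m) / v - 1)`.
#' The default goal (mean 4.0 um, sd 1.0 um on `[2.5, 9.0]`) gives
#' `alpha = 1.5`, `beta = 5.0`.
#'
#' @param goal_mean goal mean capillary diameter, um (default 4.0).
#' @param goal_sd goal standard deviation, um (default 1.0).
#' @param d_min,d_max support of the beta distribution, um (2.5, 9.0).
#' @param n_bins number of histogram bins over `[d_min, d_max]` (500).
#' @return an object of class `upscale_config` with the solved shape
#'   parameters `alpha`, `beta` and the bin edges.
#' @export
upscale_config <- function(goal_mean = 4.0, goal_sd = 1.0,
                           d_min = 2.5, d_max = 9.0, n_bins = 500L) {
  stopifnot(d_min < goal_mean, goal_mean < d_max, n_bins >= 2)
  m <- (goal_mean - d_min) / (d_max - d_min)
  v <- (goal_sd / (d_max - d_min))^2
  if (v >= m * (1 - m)) {
    stop("config error: (mean, sd) not attainable by a beta distribution ",
         "on [", d_min, ", ", d_max, "]")
  }
  k <- m * (1 - m) / v - 1
  structure(list(goal_mean = goal_mean, goal_sd = goal_sd,
                 d_min = d_min, d_max = d_max, n_bins = as.integer(n_bins),
                 alpha = m * k, beta = (1 - m) * k,
                 edges = seq(d_min, d_max, length.out = n_bins + 1)),
            class = "upscale_config")
}

#' Sample from the goal beta diameter distribution
#'
#' @param n number of samples.
#' @param config an [upscale_config()].
#' @return diameters in um.
#' @export
sample_goal_diameters <- function(n, config = upscale_config()) {
  config$d_min + (config$d_max - config$d_min) *
    stats::rbeta(n, config$alpha, config$beta)
}

#' Histogram-based upscaling of capillary diameters
#'
#' Shifts diameters upward, bin by bin, until the histogram matches a goal
#' beta distribution. The diameter range is divided into `n_bins` bins
#' (default bin width (9.0 - 2.5)/500 = 0.013 um). Processing starts at the
#' bin holding the smallest diameters. For each bin the goal count is the
#' beta probability mass of the bin times the total vessel count (rounded
#' half-up, with the rounding residual carried to the next bin so the goal
#' counts total to the number of vessels). If the bin currently holds more
#' vessels than its goal count, the surplus vessels -- those with the
#' largest diameters in the bin, above the cut diameter at which the kept
#' count equals the goal -- are shifted upward by the constant difference
#' between the bin's upper bound and the cut diameter, which places them in
#' the next bin, where they are counted again. Bins already at or below
#' their goal count are left untouched (deficits are not back-filled).
#' The procedure is fully deterministic; ties in the within-bin sort are
#' broken by input position.
#'
#' @param diameters numeric vector of diameters, um. Values below `d_min`
#'   are counted in the first bin.
#' @param config an [upscale_config()].
#' @return upscaled diameters, same length and order as the input; every
#'   output is >= its input and <= `d_max`.
#' @export
histogram_upscale <- function(diameters, config = upscale_config()) {
  n <- length(diameters)
  if (n == 0L) return(numeric(0))
  if (any(!is.finite(diameters))) stop("diameters must be finite")
  edges <- config$edges
  nb <- config$n_bins
  d <- pmin(diameters, config$d_max)

  # integer goal counts: round-half-up of beta mass x total, residual
  # carried forward so that the goal counts sum to n
  p_edges <- stats::pbeta((edges - config$d_min) / (config$d_max - config$d_min),
                          config$alpha, config$beta)
  mass <- diff(p_edges) / (p_edges[nb + 1] - p_edges[1])
  goal <- integer(nb)
  carry <- 0
  for (i in seq_len(nb)) {
    want <- mass[i] * n + carry
    goal[i] <- floor(want + 0.5)
    carry <- want - goal[i]
  }

  for (i in seq_len(nb)) {
    lo <- edges[i]; hi <- edges[i + 1]
    in_bin <- if (i == 1L) which(d < hi) else which(d >= lo & d < hi)
    if (i == nb) in_bin <- if (nb == 1L) which(d <= hi) else
      which(d >= lo & d <= hi)
    cur <- length(in_bin)
    if (cur <= goal[i]) next
    ord <- in_bin[order(d[in_bin])] # stable: ties keep input order
    if (goal[i] == 0L) {
      cut <- lo
      move <- ord
    } else {
      cut <- d[ord[goal[i]]]
      move <- ord[d[ord] > cut]
      # with tied diameters at the cut more than goal[i] vessels may stay;
      # move later-positioned ties to restore the exact goal count
      excess <- (cur - length(move)) - goal[i]
      if (excess > 0) {
        ties <- ord[d[ord] == cut]
        move <- c(ties[seq.int(length(ties) - excess + 1L, length(ties))],
                  move)
      }
    }
    if (length(move)) {
      d[move] <- pmin(d[move] + (hi - cut), config$d_max)
    }
  }
  pmax(d, diameters) # shifts are non-negative by construction
}

#' Upscale the capillary diameters of a network
#'
#' Applies [histogram_upscale()] to the vessels labeled `C`; all other
#' vessels pass through unchanged.
#'
#' @param net a [vasc_network()].
#' @param config an [upscale_config()].
#' @return the network with upscaled capillary diameters.
#' @export
upscale_network <- function(net, config = upscale_config()) {
  is_c <- net$vessels$type == "C"
  if (any(is_c)) {
    ord <- order(net$vessels$id[is_c]) # deterministic tie-break by id
    d <- net$vessels$diameter[is_c][ord]
    up <- histogram_upscale(d, config)
    net$vessels$diameter[which(is_c)[ord]] <- up
  }
  net
}
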