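#' Calibration prior on a clade's age
#'
#' Identifies an internal node by the tip set whose most recent common
#' ancestor it is, and attaches a prior density to that node's age.
#' Supported families: `normal` (mean, sd), `lognormal` (meanlog, sdlog)
#' and `uniform` (min, max). All densities are on the age scale (time
#' before present) and are treated as 0 for non-positive ages.
#'
#' @param tips character vector (>= 2) of tip labels defining the clade.
#' @param dist distribution family.
#' @param par1,par2 the two parameters, in the order given above.
#' @return object of class `calibration_prior`.
#' @export
calibration_prior <- function(tips, dist = c("normal", "lognormal", "uniform"),
                              par1, par2) {
  dist <- match.arg(dist)
  stopifnot(length(tips) >= 2L)
  if (dist == "uniform" && par2 <= par1) stop("uniform prior needs min < max")
  if (dist != "uniform" && par2 <= 0) stop("scale parameter must be positive")
  structure(list(tips = tips, dist = dist, par1 = par1, par2 = par2),
            class = "calibration_prior")
}

calib_logdens <- function(cal, x) {
  if (x <= 0) return(-Inf)
  switch(cal$dist,
         normal    = stats::dnorm(x, cal$par1, cal$par2, log = TRUE),
         lognormal = stats::dlnorm(x, cal$par1, cal$par2, log = TRUE),
         uniform   = stats::dunif(x, cal$par1, cal$par2, log = TRUE))
}

calib_draw <- function(cal, n = 1L) {
  switch(cal$dist,
         normal    = stats::rnorm(n, cal$par1, cal$par2),
         lognormal = stats::rlnorm(n, cal$par1, cal$par2),
         uniform   = stats::runif(n, cal$par1, cal$par2))
}

# normal(age, frac * age) calibrations for every internal node of a dated
# species tree -- the fixture-style prior set used in simulations
auto_calibrations <- function(st, frac = 0.05, dist = "normal") {
  phy <- st$phylo
  n <- ape::Ntip(phy)
  lapply(seq_len(phy$Nnode), function(i) {
    node <- n + i
    tips <- descendant_tips(phy, node)
    a <- st$ages[node]
    calibration_prior(tips, dist, a, max(frac * a, 1e-3))
  })
}

#' MCMC settings for the node-dating sampler
#'
#' @param chain_length total iterations (each updates one parameter block).
#' @param sample_interval thinning interval for the recorded trace.
#' @param pre_burnin iterations run (and discarded) before sampling starts;
#'   proposal step sizes are adaptively tuned only during this phase.
#' @param clock `strict` (one rate) or `ucln` (uncorrelated lognormal
#'   per-branch rate multipliers with sampled spread).
#' @param burnin_frac additional fraction of the recorded trace discarded
#'   when summarizing (tracer-style).
#' @param seed integer seed.
#' @export
dating_config <- function(chain_length = 2e5, sample_interval = 100L,
                          pre_burnin = 1e4, clock = c("strict", "ucln"),
                          burnin_frac = 0.1, seed = 1L) {
  clock <- match.arg(clock)
  stopifnot(chain_length >= sample_interval, sample_interval >= 1,
            pre_burnin >= 0, chain_length > pre_burnin,
            burnin_frac >= 0, burnin_frac < 1)
  structure(list(chain_length = as.double(chain_length),
                 sample_interval = as.integer(sample_interval),
                 pre_burnin = as.double(pre_burnin), clock = clock,
                 burnin_frac = burnin_frac, seed = as.integer(seed)),
            class = "dating_config")
}

#' Bayesian node dating of the focal Z-W divergence on a fixed topology
#'
#' Metropolis-within-Gibbs sampler over internal node ages, clock rate(s)
#' and substitution parameters on a fixed rooted gametolog topology.
#' Calibration priors constrain every internal node except the focal Z-W
#' divergence node, whose age posterior is the t_RC estimate. Node ages
#' respect the parent-older-than-child ordering by construction (uniform
#' slide proposals within the parent/child bracket; scale move for the
#' root). The posterior is likelihood x calibration densities x rate prior.
#'
#' @param aln a [dna_alignment] containing all topology tips.
#' @param topology fixed rooted binary [ape::phylo] (reference species
#'   topology plus the focal W tip); branch lengths, if any, are ignored.
#' @param calibrations list of [calibration_prior]; each must resolve to an
#'   internal node other than the focal Z-W node.
#' @param config a [dating_config].
#' @param focal_z,focal_w tip labels of the focal Z and W sequences.
#' @param model a [subst_model]; default TN93+G4 fitted frequencies. The
#'   model's exchangeabilities, gamma shape (and the clock rate) are sampled;
#'   base frequencies stay at their empirical values.
#' @param prior_only if `TRUE` the sequence likelihood is switched off
#'   (sampling from the prior; used for prior-calibration checks).
#' @param root_max upper bound for the root age when the root carries no
#'   calibration (uniform root prior on (0, root_max]).
#' @return object of class `posterior_trace`: a data frame with columns
#'   `state`, `posterior`, `likelihood`, `prior`, `focal_age`, `root_age`,
#'   `rate` (plus sampled model parameters), one row per retained sample;
#'   attributes carry the config and node bookkeeping.
#' @export
run_dating_mcmc <- function(aln, topology, calibrations, config,
                            focal_z, focal_w, model = NULL,
                            prior_only = FALSE, root_max = NULL) {
  stopifnot(inherits(config, "dating_config"))
  phy <- ape::reorder.phylo(topology, "postorder")
  phy$edge.length <- NULL
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  root <- n + 1L
  if (!all(c(focal_z, focal_w) %in% phy$tip.label))
    stop("focal tips absent from topology")
  parent <- integer(nn); parent[phy$edge[, 2]] <- phy$edge[, 1]
  children <- split(phy$edge[, 2], factor(phy$edge[, 1], levels = seq_len(nn)))
  focal_node <- ape::getMRCA(phy, c(focal_z, focal_w))

  # resolve calibrations to nodes
  calnode <- vapply(calibrations, function(cl) {
    miss <- setdiff(cl$tips, phy$tip.label)
    if (length(miss)) stop("calibration tips absent: ", paste(miss, collapse = ","))
    ape::getMRCA(phy, cl$tips)
  }, 0L)
  if (any(calnode == focal_node))
    stop("calibration placed on the focal Z-W divergence node")
  if (anyDuplicated(calnode)) stop("two calibrations resolve to one node")
  calmap <- vector("list", nn)
  for (i in seq_along(calnode)) calmap[[calnode[i]]] <- calibrations[[i]]

  if (is.null(model)) {
    model <- subst_model("TN93", bf = empirical_bf(aln), kappa1 = 4,
                         kappa2 = 4, alpha = 0.5, ncat = 4L)
  }
  ctx <- if (!prior_only) likelihood_context(aln, {
    p2 <- phy; p2$edge.length <- rep(0.1, nrow(p2$edge)); p2
  }, model) else NULL

  set.seed(config$seed)
  internal <- setdiff(seq(n + 1L, nn), integer(0))
  ages <- initial_ages(phy, n, nn, root, parent, children, calmap, root_max)
  if (is.null(root_max)) root_max <- 4 * ages[root]

  # clock-rate prior center: JC-corrected deepest pairwise distance over
  # twice the initial root age (an uncorrected or shallow distance would
  # miscenter the prior low and bias ages upward)
  r0 <- if (prior_only) 1e-3 else {
    mm <- unclass(aln)[phy$tip.label, , drop = FALSE]
    pmax <- 0
    for (i in seq_len(nrow(mm) - 1L)) for (j in seq.int(i + 1L, nrow(mm))) {
      ok <- mm[i, ] %in% c("A", "C", "G", "T") & mm[j, ] %in% c("A", "C", "G", "T")
      if (any(ok)) pmax <- max(pmax, mean(mm[i, ok] != mm[j, ok]))
    }
    dmax <- if (pmax >= 0.7) 1.5 else -3 / 4 * log(1 - 4 * pmax / 3)
    max(dmax / (2 * max(ages[root], 1e-8)), 1e-8)
  }
  state <- list(ages = ages, rate = r0, sigma = 0.3,
                mult = rep(1, nrow(phy$edge)),
                kappa1 = 4, kappa2 = 4, alpha = 0.5)
  has_tn <- model$family %in% c("TN93", "HKY85", "K80")
  has_g <- model$ncat > 1L

  mk_model <- function(s) {
    if (model$family == "TN93")
      subst_model("TN93", bf = model$bf, kappa1 = s$kappa1, kappa2 = s$kappa2,
                  alpha = if (has_g) s$alpha else 1, ncat = model$ncat,
                  pinv = model$pinv)
    else if (model$family %in% c("HKY85", "K80"))
      subst_model(model$family, bf = model$bf, kappa = s$kappa1,
                  alpha = if (has_g) s$alpha else 1, ncat = model$ncat,
                  pinv = model$pinv)
    else model
  }
  edge_child <- phy$edge[, 2]
  edge_par <- phy$edge[, 1]
  elen_of <- function(s) {
    dt <- s$ages[edge_par] - s$ages[edge_child]
    dt * s$rate * (if (config$clock == "ucln") s$mult else 1)
  }
  loglik_of <- function(s, m) {
    if (prior_only) return(0)
    prune_total_cpp(ctx$edge, ctx$ntip, ctx$nnode, ctx$root, elen_of(s),
                    ctx$tip, ctx$npat, m$eig$U, m$eig$Uinv,
                    m$eig$lambda, m$bf, m$rates, m$pinv, ctx$invprod,
                    ctx$weights)
  }
  # per-node age log-prior, precompiled to parameter vectors for speed
  cal_code <- integer(nn); cal_p1 <- numeric(nn); cal_p2 <- numeric(nn)
  for (v in internal) {
    cl <- calmap[[v]]
    if (!is.null(cl)) {
      cal_code[v] <- match(cl$dist, c("normal", "lognormal", "uniform"))
      cal_p1[v] <- cl$par1; cal_p2[v] <- cl$par2
    }
  }
  age_lp <- function(v, x) {
    if (x <= 0) return(-Inf)
    switch(cal_code[v] + 1L,
           if (v == root) stats::dunif(x, 0, root_max, log = TRUE) else 0,
           stats::dnorm(x, cal_p1[v], cal_p2[v], log = TRUE),
           stats::dlnorm(x, cal_p1[v], cal_p2[v], log = TRUE),
           stats::dunif(x, cal_p1[v], cal_p2[v], log = TRUE))
  }
  logprior_of <- function(s) {
    lp <- sum(vapply(internal, function(v) age_lp(v, s$ages[v]), 0))
    lp <- lp + stats::dlnorm(s$rate, log(r0), 2, log = TRUE)
    if (config$clock == "ucln") {
      lp <- lp + stats::dexp(s$sigma, 1, log = TRUE) +
        sum(stats::dlnorm(s$mult, -s$sigma^2 / 2, s$sigma, log = TRUE))
    }
    if (has_tn) lp <- lp + stats::dlnorm(s$kappa1, log(2), 1.5, log = TRUE) +
      stats::dlnorm(s$kappa2, log(2), 1.5, log = TRUE)
    if (has_g) lp <- lp + stats::dlnorm(s$alpha, 0, 1.5, log = TRUE)
    lp
  }

  cur_m <- mk_model(state)
  cur_ll <- loglik_of(state, cur_m)
  cur_lp <- logprior_of(state)
  tries <- 0L
  while (!is.finite(cur_ll + cur_lp) && tries < 20L) {
    state$ages <- initial_ages(phy, n, nn, root, parent, children, calmap,
                               root_max, jitter = TRUE)
    cur_ll <- loglik_of(state, cur_m); cur_lp <- logprior_of(state)
    tries <- tries + 1L
  }
  if (!is.finite(cur_ll + cur_lp))
    stop("could not find a starting state with positive posterior probability")

  # adaptive scales for multiplier moves
  sc <- c(rate = 0.4, sigma = 0.4, kappa1 = 0.3, kappa2 = 0.3, alpha = 0.3,
          root = 0.2, mult = 0.4)
  acc <- sc * 0; try_n <- sc * 0
  total <- config$chain_length
  keep <- floor((config$chain_length - config$pre_burnin) /
                  config$sample_interval)
  cols <- c("state", "posterior", "likelihood", "prior", "focal_age",
            "root_age", "rate",
            if (has_tn) c("kappa1", "kappa2"), if (has_g) "alpha",
            if (config$clock == "ucln") "sigma")
  trace <- matrix(NA_real_, keep, length(cols),
                  dimnames = list(NULL, cols))
  ti <- 0L
  scalar_moves <- c("rate", if (config$clock == "ucln") c("sigma", "mult"),
                    if (has_tn) c("kappa1", "kappa2"), if (has_g) "alpha")
  n_int <- length(internal)
  p_age <- 0.7

  for (it in seq_len(total)) {
    if (stats::runif(1) < p_age) {
      # age move: uniform slide within the parent/children bracket
      # (the bracket is unchanged by the move, so the proposal is symmetric);
      # scale move for the root
      v <- internal[sample.int(n_int, 1L)]
      lo <- max(state$ages[children[[v]]])
      old <- state$ages[v]
      if (v == root) {
        prop <- old * exp(sc["root"] * (stats::runif(1) - 0.5))
        lhr <- log(prop / old)
        ok <- prop > lo && prop <= root_max
        nm <- "root"
      } else {
        hi <- state$ages[parent[v]]
        prop <- stats::runif(1, lo, hi)
        lhr <- 0; ok <- TRUE; nm <- NA
      }
      if (ok) {
        dlp <- age_lp(v, prop) - age_lp(v, old)
        if (is.finite(dlp)) {
          state$ages[v] <- prop
          ll2 <- loglik_of(state, cur_m)
          if (is.finite(ll2) &&
              log(stats::runif(1)) < ll2 - cur_ll + dlp + lhr) {
            cur_ll <- ll2; cur_lp <- cur_lp + dlp
            if (!is.na(nm)) acc[nm] <- acc[nm] + 1
          } else state$ages[v] <- old
        }
      }
      if (!is.na(nm)) try_n[nm] <- try_n[nm] + 1
    } else {
      nm <- scalar_moves[sample.int(length(scalar_moves), 1L)]
      f <- exp(sc[nm] * (stats::runif(1) - 0.5))
      lhr <- log(f)
      if (nm == "sigma") {
        # sigma only enters the rate-multiplier prior; no likelihood change
        new <- state$sigma * f
        dlp <- stats::dexp(new, 1, log = TRUE) -
          stats::dexp(state$sigma, 1, log = TRUE) +
          sum(stats::dlnorm(state$mult, -new^2 / 2, new, log = TRUE)) -
          sum(stats::dlnorm(state$mult, -state$sigma^2 / 2, state$sigma,
                            log = TRUE))
        if (is.finite(dlp) && log(stats::runif(1)) < dlp + lhr) {
          state$sigma <- new; cur_lp <- cur_lp + dlp
          acc[nm] <- acc[nm] + 1
        }
      } else if (nm == "mult") {
        e <- sample.int(length(state$mult), 1L)
        old <- state$mult[e]; new <- old * f
        dlp <- stats::dlnorm(new, -state$sigma^2 / 2, state$sigma, log = TRUE) -
          stats::dlnorm(old, -state$sigma^2 / 2, state$sigma, log = TRUE)
        state$mult[e] <- new
        ll2 <- loglik_of(state, cur_m)
        if (is.finite(ll2 + dlp) &&
            log(stats::runif(1)) < ll2 - cur_ll + dlp + lhr) {
          cur_ll <- ll2; cur_lp <- cur_lp + dlp
          acc[nm] <- acc[nm] + 1
        } else state$mult[e] <- old
      } else {
        old <- state[[nm]]; new <- old * f
        dlp <- switch(nm,
          rate = stats::dlnorm(new, log(r0), 2, log = TRUE) -
                 stats::dlnorm(old, log(r0), 2, log = TRUE),
          kappa1 = , kappa2 = stats::dlnorm(new, log(2), 1.5, log = TRUE) -
                 stats::dlnorm(old, log(2), 1.5, log = TRUE),
          alpha = stats::dlnorm(new, 0, 1.5, log = TRUE) -
                 stats::dlnorm(old, 0, 1.5, log = TRUE))
        state[[nm]] <- new
        m2 <- if (nm %in% c("kappa1", "kappa2", "alpha")) mk_model(state)
              else cur_m
        ll2 <- loglik_of(state, m2)
        if (is.finite(ll2 + dlp) &&
            log(stats::runif(1)) < ll2 - cur_ll + dlp + lhr) {
          cur_ll <- ll2; cur_lp <- cur_lp + dlp; cur_m <- m2
          acc[nm] <- acc[nm] + 1
        } else state[[nm]] <- old
      }
      try_n[nm] <- try_n[nm] + 1
    }
    # adapt proposal scales during pre-burnin only
    if (it <= config$pre_burnin && it %% 200L == 0L) {
      for (nm2 in names(sc)) if (try_n[nm2] > 20) {
        r <- acc[nm2] / try_n[nm2]
        if (r < 0.2) sc[nm2] <- sc[nm2] * 0.8
        if (r > 0.5) sc[nm2] <- sc[nm2] * 1.25
        acc[nm2] <- 0; try_n[nm2] <- 0
      }
    }
    if (it > config$pre_burnin &&
        (it - config$pre_burnin) %% config$sample_interval == 0L) {
      ti <- ti + 1L
      if (ti <= keep)
        trace[ti, ] <- c(it, cur_ll + cur_lp, cur_ll, cur_lp,
                         state$ages[focal_node], state$ages[root], state$rate,
                         if (has_tn) c(state$kappa1, state$kappa2),
                         if (has_g) state$alpha,
                         if (config$clock == "ucln") state$sigma)
    }
  }
  out <- as.data.frame(trace[seq_len(ti), , drop = FALSE])
  attr(out, "config") <- config
  attr(out, "focal_node") <- focal_node
  attr(out, "topology") <- phy
  class(out) <- c("posterior_trace", "data.frame")
  out
}

# ordering-consistent starting ages: calibrated nodes at their prior
# centers, others interpolated; repaired bottom-up if inconsistent
initial_ages <- function(phy, n, nn, root, parent, children, calmap,
                         root_max, jitter = FALSE) {
  ages <- rep(NA_real_, nn)
  ages[seq_len(n)] <- 0
  for (v in seq(n + 1L, nn)) {
    cl <- calmap[[v]]
    if (!is.null(cl))
      ages[v] <- switch(cl$dist, normal = cl$par1,
                        lognormal = exp(cl$par1),
                        uniform = (cl$par1 + cl$par2) / 2)
  }
  if (is.na(ages[root]))
    ages[root] <- if (!is.null(root_max)) root_max / 2
                  else 2 * max(ages, na.rm = TRUE, 0) + 1
  # depth-proportional fill for remaining nodes, then ordering repair
  depth <- integer(nn)
  ord <- rev(seq_len(nrow(phy$edge)))  # preorder over edges
  for (e in ord) depth[phy$edge[e, 2]] <- depth[phy$edge[e, 1]] + 1L
  maxd <- max(depth) + 1L
  for (v in seq(n + 1L, nn))
    if (is.na(ages[v])) ages[v] <- ages[root] * (1 - depth[v] / maxd)
  if (jitter) {
    int <- seq(n + 1L, nn)
    ages[int] <- ages[int] * exp(stats::runif(length(int), -0.2, 0.2))
  }
  # bottom-up repair: parent strictly above children
  po <- seq_len(nrow(phy$edge))  # postorder edges
  for (e in po) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    if (ages[p] <= ages[ch]) ages[p] <- ages[ch] * 1.01 + 1e-6
  }
  ages
}

#' Summarize a dating trace
#'
#' Applies the summary burn-in fraction, then reports the posterior median,
#' 95% HPD and effective sample size of the focal Z-W divergence age,
#' optionally normalized by the sampled root age (per sample), putting the
#' estimate on the 0-1 scale of the reference tree.
#'
#' @param trace a `posterior_trace`.
#' @param mass HPD mass.
#' @param normalize divide each focal-age sample by its root-age sample.
#' @return object of class `dating_result`: list with `median`, `hpd_lo`,
#'   `hpd_hi`, `hpd_width`, `ess`, `n`, `normalized`, and the (possibly
#'   normalized) `samples`.
#' @export
dating_result <- function(trace, mass = 0.95, normalize = TRUE) {
  cfg <- attr(trace, "config")
  drop <- floor(nrow(trace) * if (!is.null(cfg)) cfg$burnin_frac else 0.1)
  x <- trace$focal_age[seq.int(drop + 1L, nrow(trace))]
  if (normalize)
    x <- x / trace$root_age[seq.int(drop + 1L, nrow(trace))]
  h <- hpd_interval(x, mass)
  structure(list(median = stats::median(x), hpd_lo = h[1], hpd_hi = h[2],
                 hpd_width = h[2] - h[1], ess = ess(x), n = length(x),
                 normalized = normalize, samples = x),
            class = "dating_result")
}

#' @export
print.dating_result <- function(x, ...) {
  cat(sprintf("t_RC posterior: median %.4g, 95%% HPD [%.4g, %.4g] (width %.4g), ESS %.0f\n",
              x$median, x$hpd_lo, x$hpd_hi, x$hpd_width, x$ess))
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous window of order statistics containing
#' `ceiling(mass * n)` samples.
#'
#' @param samples numeric vector (length >= 1).
#' @param mass interval mass in (0, 1].
#' @return numeric `c(lo, hi)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  if (length(samples) == 0L) stop("empty sample")
  if (mass <= 0 || mass > 1) stop("mass must be in (0, 1]")
  x <- sort(samples)
  n <- length(x)
  m <- min(n, max(1L, ceiling(mass * n)))
  i <- which.min(x[seq.int(m, n)] - x[seq_len(n - m + 1L)])
  c(lo = x[i], hi = x[i + m - 1L])
}

#' Effective sample size
#'
#' `n / (1 + 2 * sum(rho_k))` with autocorrelations summed until the first
#' non-positive term. A constant series is reported as ESS = n with a
#' warning (no autocorrelation information).
#'
#' @param samples numeric vector, length >= 10.
#' @export
ess <- function(samples) {
  n <- length(samples)
  if (n < 10L) stop("need >= 10 samples")
  if (stats::sd(samples) == 0) {
    warning("constant series; ESS reported as n")
    return(n)
  }
  rho <- stats::acf(samples, lag.max = min(n - 1L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  s <- 0
  for (r in rho) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Prune a dating problem to a subset of outgroups
#'
#' Keeps the focal species plus the `keep` outgroup species closest to it
#' (by divergence age), pruning the species tree and alignment consistently
#' and dropping calibrations whose clades are no longer fully present.
#'
#' @param st a [species_tree].
#' @param aln a [dna_alignment] (Z sequences named as tree tips; the focal W
#'   row, if any, is kept automatically).
#' @param keep number of non-focal species to retain (>= 1).
#' @param calibrations optional list of [calibration_prior] to filter.
#' @param w_suffix suffix of W tip labels.
#' @return list with pruned `st`, `aln` and `calibrations`.
#' @export
reduce_outgroups <- function(st, aln, keep, calibrations = NULL,
                             w_suffix = "_W") {
  stopifnot(inherits(st, "species_tree"))
  others <- setdiff(st$phylo$tip.label, st$focal)
  if (keep > length(others))
    stop("keep = ", keep, " exceeds available outgroups (", length(others), ")")
  # closeness = age of the MRCA with the focal species
  div <- vapply(others, function(sp)
    st$ages[ape::getMRCA(st$phylo, c(st$focal, sp))], 0)
  sel <- names(sort(div))[seq_len(keep)]
  keep_tips <- c(st$focal, sel)
  phy2 <- ape::keep.tip(st$phylo, keep_tips)
  st2 <- species_tree(phy2, focal = st$focal,
                      w_set = intersect(st$w_set, keep_tips))
  rows <- intersect(rownames(aln),
                    c(keep_tips, paste0(intersect(st$w_set, keep_tips),
                                        w_suffix)))
  aln2 <- dna_alignment(unclass(aln)[rows, , drop = FALSE])
  cal2 <- if (is.null(calibrations)) NULL else
    Filter(function(cl) all(cl$tips %in% keep_tips), calibrations)
  list(st = st2, aln = aln2, calibrations = cal2)
}
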