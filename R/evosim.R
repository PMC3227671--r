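# Sequence-pair evolution simulator: HKY substitutions with discrete-gamma
# rate heterogeneity and indels with Lavalette-distributed lengths, applied
# Gillespie-style along each of the two branches descending from a random
# root sequence; plus planting of fixed-length inversions and assembly of
# simulation sets with realignment.

BASES <- c("A", "C", "G", "T")

#' Simulator configuration
#'
#' Defaults emulate human-chimpanzee-like diverged pairs: base composition
#' (gA, gT, gC, gG) = (0.289, 0.304, 0.203, 0.204), transition/transversion
#' parameter kappa 1.75, indel/substitution ratio 0.159, gamma shape 0.65
#' with 5 discrete categories, Lavalette indel lengths (a = 2, max 50).
#' \code{subs_per_site} is the total expected number of substitutions per
#' site separating the two descendants (split equally between branches);
#' the default 0.012 matches human-chimp mismatch levels.  For the
#' AT-exclusive condition use \code{base_comp = c(A=0.5, T=0.5, C=0, G=0)}.
#'
#' @param root_length length of the random root sequence (default 5000).
#' @param base_comp named or unnamed numeric of length 4 in order A, T, C, G
#'   summing to 1.
#' @param tstv HKY transition/transversion parameter kappa.
#' @param subs_per_site expected substitutions per site between the pair.
#' @param indel_sub_ratio indel events per substitution event.
#' @param gamma_shape,gamma_categories discrete-gamma rate heterogeneity.
#' @param lavalette_a,lavalette_max indel length distribution parameters.
#' @param inversion_length length of the planted inversion (5-125).
#' @param n_pairs number of pairs in a simulation set.
#' @param seed optional RNG seed for \code{\link{make_simulation_set}}.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(root_length = 5000L,
                       base_comp = c(A = 0.289, T = 0.304, C = 0.203,
                                     G = 0.204),
                       tstv = 1.75, subs_per_site = 0.012,
                       indel_sub_ratio = 0.159, gamma_shape = 0.65,
                       gamma_categories = 5L, lavalette_a = 2,
                       lavalette_max = 50L, inversion_length = 10L,
                       n_pairs = 1L, seed = NULL) {
  stopifnot(root_length >= 1L, length(base_comp) == 4L,
            abs(sum(base_comp) - 1) < 1e-9, all(base_comp >= 0),
            tstv > 0, subs_per_site >= 0, indel_sub_ratio >= 0,
            gamma_shape > 0, gamma_categories >= 1L, lavalette_a > 0,
            lavalette_max >= 1L, n_pairs >= 1L)
  if (inversion_length < 5L || inversion_length > 125L)
    stop("inversion_length must be in [5, 125]")
  if (is.null(names(base_comp))) names(base_comp) <- c("A", "T", "C", "G")
  base_comp <- base_comp[BASES]  # internal order A, C, G, T
  structure(list(root_length = as.integer(root_length),
                 base_comp = base_comp, tstv = tstv,
                 subs_per_site = subs_per_site,
                 indel_sub_ratio = indel_sub_ratio,
                 gamma_shape = gamma_shape,
                 gamma_categories = as.integer(gamma_categories),
                 lavalette_a = lavalette_a,
                 lavalette_max = as.integer(lavalette_max),
                 inversion_length = as.integer(inversion_length),
                 n_pairs = as.integer(n_pairs), seed = seed),
            class = "sim_config")
}

#' HKY85 instantaneous rate matrix
#'
#' Rates are normalised to one expected substitution per site per unit
#' branch length at stationarity; rows sum to zero.  Bases with zero
#' stationary frequency are unreachable (their columns are zero), which
#' turns the AT-exclusive composition into a two-state A/T chain.
#'
#' @param base_comp stationary frequencies, order A, C, G, T (or named).
#' @param tstv transition/transversion parameter kappa.
#' @return 4x4 matrix with dimnames A, C, G, T.
#' @export
hky_rate_matrix <- function(base_comp, tstv) {
  if (!is.null(names(base_comp))) base_comp <- base_comp[BASES]
  stopifnot(length(base_comp) == 4L, abs(sum(base_comp) - 1) < 1e-9,
            all(base_comp >= 0), tstv > 0)
  pi <- as.numeric(base_comp)
  is_transition <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
  is_transition["A", "G"] <- is_transition["G", "A"] <- TRUE
  is_transition["C", "T"] <- is_transition["T", "C"] <- TRUE
  Q <- matrix(rep(pi, each = 4), 4, 4, dimnames = list(BASES, BASES))
  Q[is_transition] <- Q[is_transition] * tstv
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate composition: no substitutions possible")
  Q / mu
}

#' Discrete-gamma rate category means
#'
#' Mean rates of \code{categories} equal-probability bins of a
#' Gamma(shape, rate = shape) distribution (mean 1).
#'
#' @param shape gamma shape parameter.
#' @param categories number of categories.
#' @return numeric vector of category rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, categories) {
  stopifnot(shape > 0, categories >= 1L)
  if (categories == 1L) return(1)
  k <- categories
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  # E[X; bin] via the Gamma(shape+1, shape) cdf identity (mean of X is 1)
  k * diff(pgamma(b, shape = shape + 1, rate = shape))
}

#' Sample per-site gamma category rates
#'
#' @param n number of sites.
#' @param shape,categories discrete-gamma parameters.
#' @return list with integer \code{category} and numeric \code{rate} per
#'   site, and the category \code{rates} table.
#' @export
sample_gamma_category_rates <- function(n, shape, categories) {
  rates <- discrete_gamma_rates(shape, categories)
  cat <- sample.int(length(rates), n, replace = TRUE)
  list(category = cat, rate = rates[cat], rates = rates)
}

#' Lavalette indel length distribution
#'
#' Probability mass proportional to \eqn{(l M / (M - l + 1))^{-a}} for
#' \eqn{l = 1, \dots, M}.
#'
#' @param a decay parameter.
#' @param max_len maximum indel length M.
#' @return normalised probability vector of length \code{max_len}.
#' @export
lavalette_probs <- function(a, max_len) {
  stopifnot(a > 0, max_len >= 1L)
  l <- seq_len(max_len)
  w <- (l * max_len / (max_len - l + 1))^(-a)
  w / sum(w)
}

#' Sample Lavalette-distributed indel lengths
#'
#' @param n number of draws.
#' @param a,max_len distribution parameters.
#' @return integer lengths in [1, max_len].
#' @export
lavalette_sample <- function(n, a, max_len) {
  if (max_len == 1L) return(rep(1L, n))
  sample.int(max_len, n, replace = TRUE, prob = lavalette_probs(a, max_len))
}

# Transition probability matrices P(t) from the eigendecomposition of Q.
hky_eigen <- function(Q) {
  e <- eigen(Q)
  list(V = e$vectors, Vi = solve(e$vectors), lambda = e$values)
}

transition_probs <- function(eg, t) {
  P <- Re(eg$V %*% diag(exp(eg$lambda * t), 4) %*% eg$Vi)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Apply CTMC substitutions to integer-coded sites over elapsed time dt,
# grouped by (gamma category, current base).
apply_substitutions <- function(seq_int, cat, dt, eg, gamma_rates) {
  for (k in unique(cat)) {
    P <- transition_probs(eg, dt * gamma_rates[k])
    sel <- cat == k
    for (b in unique(seq_int[sel])) {
      idx <- which(sel & seq_int == b)
      seq_int[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                 prob = P[b, ])
    }
  }
  seq_int
}

# Evolve one branch for time t: indel events arrive as a Poisson process with
# per-site rate indel_sub_ratio (relative to substitution rate 1); CTMC
# substitutions run between events.
evolve_branch <- function(seq_int, cat, t, cfg, eg, gamma_rates) {
  pi <- as.numeric(cfg$base_comp)
  time_left <- t
  repeat {
    L <- length(seq_int)
    if (L == 0L) stop("sequence deleted to extinction")
    rate <- cfg$indel_sub_ratio * L
    tau <- if (rate > 0) rexp(1, rate) else Inf
    if (tau >= time_left) {
      if (time_left > 0)
        seq_int <- apply_substitutions(seq_int, cat, time_left, eg,
                                       gamma_rates)
      break
    }
    seq_int <- apply_substitutions(seq_int, cat, tau, eg, gamma_rates)
    time_left <- time_left - tau
    len <- lavalette_sample(1L, cfg$lavalette_a, cfg$lavalette_max)
    if (runif(1) < 0.5) {  # deletion, truncated at the sequence end
      start <- sample.int(L, 1L)
      drop <- start:min(L, start + len - 1L)
      seq_int <- seq_int[-drop]; cat <- cat[-drop]
    } else {  # insertion after a uniform position in 0..L
      pos <- sample.int(L + 1L, 1L) - 1L
      ins <- sample.int(4L, len, replace = TRUE, prob = pi)
      ins_cat <- sample.int(length(gamma_rates), len, replace = TRUE)
      seq_int <- append(seq_int, ins, after = pos)
      cat <- append(cat, ins_cat, after = pos)
    }
  }
  list(seq = seq_int, cat = cat)
}

int_to_seq <- function(x) paste(BASES[x], collapse = "")

#' Evolve one diverged sequence pair (no inversion planted)
#'
#' Draws a root sequence i.i.d. from the base composition and evolves two
#' descendant copies independently for \code{subs_per_site / 2} substitutions
#' per site each, with per-site discrete-gamma rates (shared for inherited
#' sites) and interleaved indels.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return object of class \code{sim_pair}: seq_a, seq_b (ungapped strings),
#'   truth_start/truth_end/inversion_length (NA until
#'   \code{\link{plant_inversion}}).
#' @export
evolve_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pi <- as.numeric(cfg$base_comp)
  root <- sample.int(4L, cfg$root_length, replace = TRUE, prob = pi)
  gamma_rates <- discrete_gamma_rates(cfg$gamma_shape, cfg$gamma_categories)
  cat <- sample.int(length(gamma_rates), cfg$root_length, replace = TRUE)
  t_branch <- cfg$subs_per_site / 2
  if (t_branch > 0 || cfg$indel_sub_ratio > 0) {
    eg <- hky_eigen(hky_rate_matrix(cfg$base_comp, cfg$tstv))
    a <- evolve_branch(root, cat, t_branch, cfg, eg, gamma_rates)
    b <- evolve_branch(root, cat, t_branch, cfg, eg, gamma_rates)
  } else {
    a <- b <- list(seq = root)
  }
  structure(list(seq_a = int_to_seq(a$seq), seq_b = int_to_seq(b$seq),
                 truth_start = NA_integer_, truth_end = NA_integer_,
                 inversion_length = NA_integer_),
            class = "sim_pair")
}

#' Plant a fixed-length inversion into seq_b
#'
#' Replaces a uniformly placed segment of \code{seq_b} by its reverse
#' complement and records the truth interval (0-based half-open).
#'
#' @param sim a \code{sim_pair}.
#' @param length inversion length in bp.
#' @return the modified \code{sim_pair} with truth fields set.
#' @export
plant_inversion <- function(sim, length) {
  L <- nchar(sim$seq_b)
  length <- as.integer(length)
  if (length > L) stop("inversion longer than the sequence")
  start <- sample.int(L - length + 1L, 1L) - 1L
  seg <- substr(sim$seq_b, start + 1L, start + length)
  sim$seq_b <- paste0(substr(sim$seq_b, 1L, start), reverse_complement(seg),
                      substr(sim$seq_b, start + length + 1L, L))
  sim$truth_start <- start
  sim$truth_end <- start + length
  sim$inversion_length <- length
  sim
}

#' Generate a reproducible simulation set with planted inversions
#'
#' For each pair: evolve, plant one inversion of \code{cfg$inversion_length}
#' in seq_b, realign (see \code{\link{realign_pair}}), and return both the
#' truth and the realigned \code{\link{gapped_pair}}.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param engine realignment engine, \code{"internal"} or \code{"mafft"}.
#' @param scoring internal-aligner scoring (see \code{\link{align_scoring}}).
#' @param plant plant inversions? (FALSE gives null pairs for false-positive
#'   estimation).
#' @return list of records, each \code{list(sim = sim_pair, pair =
#'   gapped_pair)}.
#' @export
make_simulation_set <- function(cfg, engine = c("internal", "mafft"),
                                scoring = align_scoring(), plant = TRUE) {
  engine <- match.arg(engine)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- vector("list", cfg$n_pairs)
  for (i in seq_len(cfg$n_pairs)) {
    sim <- evolve_pair(cfg)
    if (plant) sim <- plant_inversion(sim, cfg$inversion_length)
    pair <- realign_pair(sim$seq_a, sim$seq_b, engine = engine,
                         scoring = scoring, id = paste0("sim", i))
    out[[i]] <- list(sim = sim, pair = pair)
  }
  out
}
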