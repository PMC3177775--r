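# Synthetic case-control genotype generator.  Noise loci are drawn in
# Hardy-Weinberg proportions from per-locus minor-allele frequencies;
# disease status comes from a penetrance table over a set of causal loci;
# retrospective case-control ascertainment is emulated by rejection
# sampling until the case and control quotas are filled.

#' Specify a penetrance-model simulation
#'
#' @param n_cases,n_controls numbers of cases and controls to ascertain.
#' @param p total number of loci.
#' @param maf per-locus minor-allele frequencies in (0, 0.5]; a scalar is
#'   recycled to all `p` loci.
#' @param causal indices of the causal loci (may be empty for a pure null
#'   model).
#' @param penetrance disease probability per causal genotype combination:
#'   a single number when `causal` is empty (constant penetrance, status
#'   independent of genotype), otherwise an array with one dimension of
#'   size `length(levels)` per causal locus (a 3 x 3 matrix for a
#'   two-locus model), indexed by minor-allele count + 1.
#' @param levels genotype codes emitted by the generator (default `0:2`,
#'   the minor-allele count).
#' @return An object of class `sim_spec`.
#' @seealso [simulate_mdr()], [xor_penetrance()], [mdr1_spec()]
#' @export
sim_spec <- function(n_cases, n_controls, p, maf = 0.3, causal = integer(0),
                     penetrance = 0.5, levels = 0:2) {
  if (length(maf) == 1L) maf <- rep(maf, p)
  if (length(maf) != p) stop("'maf' must be a scalar or have one entry per locus")
  if (any(maf <= 0 | maf > 0.5)) stop("minor-allele frequencies must lie in (0, 0.5]")
  causal <- as.integer(causal)
  if (anyDuplicated(causal) || any(causal < 1L | causal > p))
    stop("'causal' must be distinct locus indices in 1..p")
  k <- length(causal)
  if (k == 0L) {
    if (length(penetrance) != 1L)
      stop("with no causal loci, 'penetrance' must be a single rate")
  } else {
    penetrance <- as.array(penetrance)
    if (!identical(dim(penetrance), rep(length(levels), k)) &&
        !(k == 1L && length(penetrance) == length(levels)))
      stop("'penetrance' must have one dimension of size ", length(levels),
           " per causal locus")
  }
  if (any(penetrance < 0 | penetrance > 1))
    stop("penetrance values must lie in [0, 1]")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 p = as.integer(p), maf = maf, causal = causal,
                 penetrance = penetrance, levels = levels),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Simulation spec:", x$n_cases, "cases /", x$n_controls, "controls,",
      x$p, "loci\n")
  if (length(x$causal) == 0L) {
    cat("  null model, constant penetrance", x$penetrance, "\n")
  } else {
    cat("  causal loci:", paste(x$causal, collapse = ", "),
        " penetrance range [", min(x$penetrance), ",", max(x$penetrance), "]\n")
  }
  invisible(x)
}

#' Two-locus XOR penetrance table
#'
#' A 3 x 3 penetrance table encoding a pure interaction: cells where
#' exactly one of the two loci is heterozygous carry `base + effect`, all
#' other cells `base`.  At minor-allele frequency 0.5 the single-locus
#' marginal penetrances are identical across genotypes, so neither locus
#' shows a main effect.
#'
#' @param base baseline disease probability.
#' @param effect added probability in the interaction cells;
#'   `base + effect` must stay within \[0, 1\].
#' @return 3 x 3 numeric matrix indexed by minor-allele count + 1.
#' @examples
#' xor_penetrance(0.1, 0.4)
#' @export
xor_penetrance <- function(base = 0.1, effect = 0.2) {
  if (base < 0 || effect < 0 || base + effect > 1)
    stop("need 0 <= base and base + effect <= 1")
  pen <- matrix(base, 3L, 3L)
  pen[2L, c(1L, 3L)] <- base + effect
  pen[c(1L, 3L), 2L] <- base + effect
  pen
}

#' Specification emulating the package's benchmark dataset shape
#'
#' A balanced retrospective sample of 125 cases and 125 controls genotyped
#' at 25 SNPs, with a two-locus pure (XOR-type) interaction embedded at
#' loci 4 and 9 (minor-allele frequency 0.5 at the causal pair, 0.3 at
#' noise loci).  Defaults give a detectable but moderate signal, the
#' regime in which internal validation is informative.
#'
#' @param n_cases,n_controls sample sizes (default 125 each).
#' @param p total loci (default 25).
#' @param causal causal locus pair (default `c(4, 9)`).
#' @param base,effect penetrance parameters passed to [xor_penetrance()].
#' @param maf_noise minor-allele frequency of the noise loci.
#' @return A [sim_spec] object.
#' @export
mdr1_spec <- function(n_cases = 125, n_controls = 125, p = 25,
                      causal = c(4, 9), base = 0.1, effect = 0.2,
                      maf_noise = 0.3) {
  maf <- rep(maf_noise, p)
  maf[causal] <- 0.5
  sim_spec(n_cases, n_controls, p, maf = maf, causal = causal,
           penetrance = xor_penetrance(base, effect))
}

#' Simulate a retrospective case-control genotype dataset
#'
#' Genotypes are drawn independently per locus in Hardy-Weinberg
#' proportions from the spec's minor-allele frequencies; disease status is
#' Bernoulli with probability given by the penetrance table at the causal
#' genotypes; individuals are accumulated by rejection sampling until
#' exactly `n_cases` cases and `n_controls` controls are ascertained.
#'
#' @param spec a [sim_spec] object.
#' @param seed optional integer seed.
#' @param max_batches safety cap on rejection-sampling rounds before
#'   declaring the quotas unreachable.
#' @return An [mdr_data] object with locus names `"1" ... "p"`, cases
#'   first.
#' @examples
#' d <- simulate_mdr(mdr1_spec(), seed = 1)
#' d
#' @export
simulate_mdr <- function(spec, seed = NULL, max_batches = 1000L) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  L <- length(spec$levels)
  k <- length(spec$causal)
  hw <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)
  need_ca <- spec$n_cases
  need_co <- spec$n_controls
  got_ca <- got_co <- NULL
  batch <- max(1000L, 2L * (need_ca + need_co))
  for (b in seq_len(max_batches)) {
    g <- matrix(0L, nrow = batch, ncol = spec$p)
    for (j in seq_len(spec$p))
      g[, j] <- sample.int(3L, batch, replace = TRUE, prob = hw(spec$maf[j])) - 1L
    risk <- if (k == 0L) rep.int(spec$penetrance, batch)
            else spec$penetrance[g[, spec$causal, drop = FALSE] + 1L]
    status <- stats::rbinom(batch, 1L, risk)
    if (need_ca > 0L) {
      take <- utils::head(which(status == 1L), need_ca)
      got_ca <- rbind(got_ca, g[take, , drop = FALSE])
      need_ca <- need_ca - length(take)
    }
    if (need_co > 0L) {
      take <- utils::head(which(status == 0L), need_co)
      got_co <- rbind(got_co, g[take, , drop = FALSE])
      need_co <- need_co - length(take)
    }
    if (need_ca == 0L && need_co == 0L) break
  }
  if (need_ca > 0L || need_co > 0L)
    stop("could not ascertain the requested cases/controls within ",
         max_batches, " sampling rounds; is the penetrance degenerate?")
  geno <- rbind(got_ca, got_co)
  geno <- matrix(spec$levels[geno + 1L], nrow = nrow(geno))
  mdr_data(geno,
           status = rep(c(1L, 0L), c(spec$n_cases, spec$n_controls)),
           levels = spec$levels,
           locus_names = as.character(seq_len(spec$p)))
}
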