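# Synthetic genotypes, crossing designs and weather.

#' Simulate an inbred parental genotype panel
#'
#' Biallelic markers are drawn independently with allele frequencies uniform
#' on `maf_range`. Individuals are near-homozygous: each call is 0 or 2 by a
#' Bernoulli draw on the allele frequency, with heterozygotes injected at
#' rate `het_rate` (default below the 1 percent panel filter, matching
#' inbred lines). Optional missingness is injected completely at random.
#'
#' @param n_individuals,n_markers panel dimensions.
#' @param maf_range length-2 interval within (0, 0.5\] for allele
#'   frequencies.
#' @param seed integer seed (bit-reproducible output).
#' @param het_rate heterozygote rate (0 gives calls in {0, 2} only).
#' @param missing_rate fraction of calls set to NA.
#' @param prefix id prefix for row names.
#' @return Genotype matrix (individuals x markers, 0/1/2/NA) with attribute
#'   `allele_freqs`.
#' @export
simulate_parents <- function(n_individuals, n_markers, maf_range = c(0.05, 0.5),
                             seed = 1, het_rate = 0.002, missing_rate = 0,
                             prefix = "P") {
  if (n_markers < 1 || n_individuals < 1)
    stop("n_individuals and n_markers must be >= 1", call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (het_rate < 0 || het_rate > 1 || missing_rate < 0 || missing_rate >= 1)
    stop("het_rate and missing_rate must be valid proportions", call. = FALSE)
  with_seed(seed, {
    p <- stats::runif(n_markers, maf_range[1], maf_range[2])
    # homozygous draws: allele dosage 2 with probability p
    g <- matrix(2 * stats::rbinom(n_individuals * n_markers, 1,
                                  rep(p, each = n_individuals)),
                nrow = n_individuals)
    if (het_rate > 0) {
      het <- matrix(stats::runif(length(g)) < het_rate, nrow = n_individuals)
      g[het] <- 1
    }
    if (missing_rate > 0) {
      g[matrix(stats::runif(length(g)) < missing_rate,
               nrow = n_individuals)] <- NA
    }
    dimnames(g) <- list(paste0(prefix, seq_len(n_individuals)),
                        paste0("m", seq_len(n_markers)))
    attr(g, "allele_freqs") <- p
    g
  })
}

#' Simulate a hybrid crossing design
#'
#' Draws `n_hybrids` distinct (mother, father) pairs uniformly without
#' replacement from the full factorial of the two panels.
#'
#' @param maternal,paternal parental genotype matrices (row names are ids).
#' @param n_hybrids number of crosses to draw.
#' @param seed integer seed.
#' @return Pedigree data.frame with columns `hybrid_id`, `mother_id`,
#'   `father_id`.
#' @export
simulate_hybrids <- function(maternal, paternal, n_hybrids, seed = 1) {
  mothers <- rownames(maternal)
  fathers <- rownames(paternal)
  if (length(mothers) == 0 || length(fathers) == 0)
    stop("both parental panels must be non-empty", call. = FALSE)
  n_cross <- length(mothers) * length(fathers)
  if (n_hybrids > n_cross)
    stop(sprintf("n_hybrids (%d) exceeds the %d possible crosses",
                 n_hybrids, n_cross), call. = FALSE)
  with_seed(seed, {
    pick <- sample.int(n_cross, n_hybrids)
    mi <- ((pick - 1) %% length(mothers)) + 1
    fi <- ((pick - 1) %/% length(mothers)) + 1
    data.frame(hybrid_id = sprintf("H%03d", seq_len(n_hybrids)),
               mother_id = mothers[mi], father_id = fathers[fi],
               stringsAsFactors = FALSE)
  })
}

#' Simulate a daily weather table for one temperate growing season
#'
#' Daily mean temperature follows a seasonal sine curve (cool around
#' planting, warm mid-season) with day-to-day noise; the diurnal range is
#' drawn per day. Early-season days commonly have Tmin < 10 degree C and
#' mid-season days commonly have Tmax > 30 degree C, so both caps of the
#' GDD formula are exercised.
#'
#' @param planting_date first day of the table.
#' @param n_days number of days.
#' @param seed integer seed.
#' @return data.frame with columns `date`, `tmin`, `tmax` (`tmin <= tmax`).
#' @export
simulate_weather <- function(planting_date = as.Date("2016-05-10"),
                             n_days = 150, seed = 1) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  with_seed(seed, {
    d <- seq_len(n_days)
    tmean <- 13 + 12 * sin(pi * pmin(d + 15, 190) / 190) +
      stats::rnorm(n_days, 0, 3)
    range_ <- pmax(4, 10 + stats::rnorm(n_days, 0, 2))
    data.frame(date = as.Date(planting_date) + d - 1,
               tmin = round(tmean - range_ / 2, 2),
               tmax = round(tmean + range_ / 2, 2))
  })
}

#' Randomized complete block field layout
#'
#' Every hybrid appears exactly once in each replicate block.
#'
#' @param hybrid_ids vector of hybrid ids.
#' @param n_reps number of replicate blocks (default 2).
#' @param site_year label for the trial.
#' @return data.frame with columns `plot_id`, `hybrid_id`, `replicate`,
#'   `site_year`.
#' @export
make_field_layout <- function(hybrid_ids, n_reps = 2, site_year = "SIM") {
  if (length(hybrid_ids) == 0) stop("no hybrids supplied", call. = FALSE)
  reps <- paste0("rep", seq_len(n_reps))
  out <- expand.grid(hybrid_id = hybrid_ids, replicate = reps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$site_year <- site_year
  out$plot_id <- sprintf("%s_%s_%s", site_year, out$replicate, out$hybrid_id)
  out[, c("plot_id", "hybrid_id", "replicate", "site_year")]
}
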