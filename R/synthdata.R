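# Synthetic inputs with known ground truth for every pipeline stage.
#
# All generators draw from R's RNG under an explicit seed (withr::with_seed,
# no global state left behind), so identical seed + parameters reproduce
# byte-identical outputs.

with_seed_ <- function(seed, code) {
  sk_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single integer", "bad-seed")
  withr::with_seed(as.integer(seed), code)
}

#' Generate a toy Calpha-only structure
#'
#' Geometries: `"helix"` places residues on an ideal alpha-helix (rise 1.5 A
#' per residue, 100 degrees per residue, radius 2.3 A, giving consecutive
#' Calpha separations of ~3.8 A); `"extended"` is a straight 3.8 A-step
#' chain; `"random-walk"` takes fixed 3.8 A steps in uniformly random
#' directions, producing the broad distance spectrum needed to plant
#' crosslink sets.
#'
#' @param n_residues number of residues (>= 2).
#' @param geometry "helix", "extended" or "random-walk".
#' @param seed RNG seed (required for "random-walk").
#' @param resnames 3-letter residue code(s), recycled (default "ALA"; use
#'   "LYS" for crosslinkable toy models).
#' @param chain chain id.
#' @param start_resnum author number of the first residue.
#' @return a [structure_model()].
#' @export
make_toy_structure <- function(n_residues, geometry = c("helix", "extended", "random-walk"),
                               seed = 1L, resnames = "ALA", chain = "A",
                               start_resnum = 1L) {
  geometry <- match.arg(geometry)
  n <- as.integer(n_residues)
  sk_assert(n >= 2L, "need at least 2 residues", "bad-n")
  co <- switch(geometry,
    helix = {
      i <- seq_len(n) - 1L
      th <- i * 100 * pi / 180
      cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
    },
    extended = cbind(3.8 * (seq_len(n) - 1), 0, 0),
    `random-walk` = with_seed_(seed, {
      # uniform directions on the sphere, fixed 3.8 A steps
      z <- stats::runif(n - 1, -1, 1)
      phi <- stats::runif(n - 1, 0, 2 * pi)
      r <- sqrt(1 - z^2)
      steps <- 3.8 * cbind(r * cos(phi), r * sin(phi), z)
      rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    })
  )
  res <- data.frame(chain = chain,
                    resnum = seq.int(start_resnum, length.out = n),
                    insert = "",
                    resname = rep_len(toupper(resnames), n),
                    x = co[, 1], y = co[, 2], z = co[, 3],
                    has_ca = TRUE, stringsAsFactors = FALSE)
  structure_model(res, id = paste0("toy-", geometry, "-", n))
}

#' Plant a crosslink set with a known satisfied fraction
#'
#' Samples residue pairs of the requested residue type from `model` such that
#' exactly `round(satisfied_fraction * n_links)` pairs have a Calpha
#' separation inside the band and the rest fall outside it. All links carry
#' `fdr <= fdr_max`, so the set survives the standard 5% link-level filter.
#'
#' @param model a [structure_model()].
#' @param n_links number of links.
#' @param satisfied_fraction target in-band fraction in `[0, 1]`.
#' @param band inclusive `c(dmin, dmax)` in Angstrom.
#' @param residue_code 1-letter code required at both ends (default "K").
#' @param seed RNG seed.
#' @param fdr_max upper bound for the sampled FDR values.
#' @return list: `records` ([crosslink_records()]) and `ground_truth`
#'   (`n_in_band`, `fraction`, `band`).
#' @export
make_crosslinks <- function(model, n_links, satisfied_fraction, band = c(15, 30),
                            residue_code = "K", seed = 1L, fdr_max = 0.05) {
  sk_assert(satisfied_fraction >= 0 && satisfied_fraction <= 1,
            "satisfied_fraction must lie in [0, 1]", "bad-fraction")
  r <- model$residues
  elig <- which(r$has_ca & aa3_to_1(r$resname) %in% residue_code)
  sk_assert(length(elig) >= 2, "model has too few residues of the requested type",
            "infeasible")
  with_seed_(seed, {
    pairs <- t(utils::combn(elig, 2))
    if (nrow(pairs) > 50000) pairs <- pairs[sample.int(nrow(pairs), 50000), ]
    d <- sqrt(rowSums((as.matrix(r[pairs[, 1], c("x", "y", "z")]) -
                       as.matrix(r[pairs[, 2], c("x", "y", "z")]))^2))
    inside <- which(d >= band[1] & d <= band[2])
    outside <- which(d < band[1] | d > band[2])
    n_in <- round(satisfied_fraction * n_links)
    n_out <- n_links - n_in
    sk_assert(length(inside) >= n_in && length(outside) >= n_out,
              sprintf("geometry cannot supply %d in-band and %d out-of-band pairs",
                      n_in, n_out), "infeasible")
    pick <- c(inside[sample.int(length(inside), n_in)],
              outside[sample.int(length(outside), n_out)])
    pick <- pick[sample.int(length(pick))]
    sel <- pairs[pick, , drop = FALSE]
    rec <- crosslink_records(pos_a = r$resnum[sel[, 1]], pos_b = r$resnum[sel[, 2]],
                             res_a = aa3_to_1(r$resname[sel[, 1]]),
                             res_b = aa3_to_1(r$resname[sel[, 2]]),
                             fdr = stats::runif(n_links, 0, fdr_max),
                             score = stats::runif(n_links, 5, 30))
    list(records = rec,
         ground_truth = list(n_in_band = n_in, fraction = n_in / n_links,
                             band = band))
  })
}

#' Generate an alignment with controlled per-column conservation
#'
#' Column `c` of each derived sequence matches the base sequence with
#' probability `per_column_identity[c]`; substitutions are uniform over the
#' other 19 residues. No gaps are introduced, so the sequences are aligned by
#' construction.
#'
#' @param base_sequence amino-acid string.
#' @param n_sequences number of sequences to emit.
#' @param per_column_identity identity probabilities in `[0, 1]`, recycled to
#'   the sequence length.
#' @param seed RNG seed.
#' @return named character vector of aligned sequences.
#' @export
make_msa <- function(base_sequence, n_sequences, per_column_identity = 1,
                     seed = 1L) {
  base <- split_residues(base_sequence)
  L <- length(base)
  p <- rep_len(per_column_identity, L)
  sk_assert(all(p >= 0 & p <= 1), "identities must lie in [0, 1]", "bad-identity")
  aas <- names(.KD)
  with_seed_(seed, {
    seqs <- vapply(seq_len(n_sequences), function(s) {
      keep <- stats::runif(L) < p
      out <- base
      if (any(!keep))
        out[!keep] <- vapply(base[!keep],
                             function(a) sample(setdiff(aas, a), 1), character(1))
      paste(out, collapse = "")
    }, character(1))
    setNames(seqs, paste0("seq", seq_len(n_sequences)))
  })
}

#' Plant a mutation table with known severity clustering
#'
#' Emits `n_total` missense records of which exactly `n_severe` carry
#' `cadd > 20` and exactly `n_in_target` of the severe ones fall in the
#' target domains; all positions are distinct and reference-consistent. The
#' default counts mirror the observed clustering of 21 of 28 severe
#' mutations in the four E3 sub-domains.
#'
#' @param n_total,n_severe,n_in_target planted counts
#'   (`n_in_target <= n_severe <= n_total`).
#' @param domain_table a [domain_table()].
#' @param target_domains domain names receiving the clustered severe records.
#' @param level hierarchy level of the target domains.
#' @param reference optional reference amino-acid string covering the table's
#'   full range; generated randomly when `NULL`.
#' @param seed RNG seed.
#' @param cadd_severe,cadd_benign sampling ranges for CADD scores; the severe
#'   range must stay strictly above 20 and the benign one at or below it.
#' @return list: `records` (`mutation_records` with `cadd` and
#'   `mapped_position` filled), `reference`, `ground_truth`
#'   (`n_severe`, `n_in_target`).
#' @export
make_mutation_table <- function(n_total = 50L, n_severe = 28L, n_in_target = 21L,
                                domain_table = rnf213_domains(),
                                target_domains = e3_subdomains(),
                                level = "subdomain", reference = NULL,
                                seed = 1L, cadd_severe = c(20.5, 40),
                                cadd_benign = c(0, 19.5)) {
  sk_assert(n_in_target <= n_severe && n_severe <= n_total,
            "need n_in_target <= n_severe <= n_total", "infeasible")
  sk_assert(cadd_severe[1] > 20 && cadd_benign[2] <= 20,
            "CADD ranges must respect the severe threshold of 20", "bad-cadd")
  L <- max(domain_table$end)
  tgt <- domain_residues(domain_table, target_domains, level)
  non_tgt <- setdiff(seq_len(L), tgt)
  sk_assert(length(tgt) >= n_in_target,
            "target domains too small for the requested count", "infeasible")
  sk_assert(length(non_tgt) >= n_total - n_in_target,
            "non-target region too small", "infeasible")
  with_seed_(seed, {
    if (is.null(reference))
      reference <- paste(sample(names(.KD), L, replace = TRUE), collapse = "")
    pos_in <- tgt[sample.int(length(tgt), n_in_target)]
    pos_out <- non_tgt[sample.int(length(non_tgt), n_total - n_in_target)]
    # order: clustered severe, remaining severe, benign -> the first
    # n_severe positions receive the severe CADD draws below
    pos <- c(pos_in, pos_out)
    refaa <- strsplit(toupper(reference), "")[[1]][pos]
    altaa <- vapply(refaa, function(a) sample(setdiff(names(.KD), a), 1), character(1))
    cadd <- c(stats::runif(n_severe, cadd_severe[1], cadd_severe[2]),
              stats::runif(n_total - n_severe, cadd_benign[1], cadd_benign[2]))
    ord <- sample.int(n_total)
    rec <- parse_hgvs_p(paste0("p.", refaa, pos, altaa)[ord])
    rec$cadd <- cadd[ord]
    rec$mapped_position <- rec$position
    rec$severity_bin <- bin_severity(rec$cadd)
    rec$domain <- assign_domain(rec$mapped_position, domain_table, level)
    list(records = rec, reference = reference,
         ground_truth = list(n_severe = n_severe, n_in_target = n_in_target))
  })
}

#' Simulate an NADH-coupled ATPase trace
#'
#' NADH decays linearly at `rate * enzyme_conc` uM per minute (one NADH per
#' hydrolyzed ATP) from `nadh0` until exhausted, is converted to fluorescence
#' through the calibration line, and perturbed with multiplicative Gaussian
#' noise. Defaults follow the assay conditions: 0.1 uM enzyme, 50 uM NADH,
#' readings over 12 h.
#'
#' @param rate ATP per enzyme per minute (>= 0).
#' @param enzyme_conc enzyme concentration, uM.
#' @param calibration a [fit_calibration()]-like list (`slope`, `intercept`).
#' @param nadh0 starting NADH concentration, uM.
#' @param duration total time, minutes.
#' @param dt sampling interval, minutes.
#' @param noise_sd multiplicative noise standard deviation (fraction).
#' @param ring_count AAA rings per molecule.
#' @param seed RNG seed.
#' @return list: `trace` ([assay_trace()]) and `ground_truth` (`rate`,
#'   `slope_au_per_min`, `exhaustion_time`).
#' @export
make_nadh_trace <- function(rate, enzyme_conc = 0.1,
                            calibration = list(slope = 100, intercept = 50),
                            nadh0 = 50, duration = 720, dt = 2,
                            noise_sd = 0.01, ring_count = 1L, seed = 1L) {
  sk_assert(rate >= 0, "rate must be >= 0", "bad-rate")
  t <- seq(0, duration, by = dt)
  nadh <- pmax(0, nadh0 - rate * enzyme_conc * t)
  signal <- calibration$slope * nadh + calibration$intercept
  with_seed_(seed, {
    if (noise_sd > 0) signal <- signal * (1 + stats::rnorm(length(signal), 0, noise_sd))
    list(trace = assay_trace(t, signal, enzyme_conc, ring_count),
         ground_truth = list(rate = rate,
                             slope_au_per_min = -calibration$slope * rate * enzyme_conc,
                             exhaustion_time = if (rate > 0) nadh0 / (rate * enzyme_conc) else Inf))
  })
}
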