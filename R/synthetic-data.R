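#' Configuration for the synthetic population generator
#'
#' Describes a multi-group panel in the style of the rice diversity panels
#' used for genomic prediction: a few large training groups plus small,
#' more diverged holdout groups, genotyped for SNPs and five classes of
#' structural variants (MITE-DTX and RLX-RIX transposon insertion
#' polymorphisms, deletions, duplications, inversions).
#'
#' Group divergence follows the Balding-Nichols model: for a marker with
#' ancestral frequency p, each group's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so F acts as a single Fst-like dial.
#' Holdout groups (by default the last two labels, standing in for the
#' aromatic and admixed rice groups) use `fst * holdout_fst_multiplier`,
#' reproducing the "distant holdout" difficulty of across-population
#' prediction.
#'
#' SV-SNP linkage is planted explicitly: a linked SV column is a copy of a
#' (fully homozygous) partner SNP column with flip noise calibrated by
#' bisection so the realized dosage r-squared hits the requested target.
#'
#' @param n_per_group named integer vector, accessions per group. Defaults
#'   to the 738-accession five-group layout (IND 451, JAP 166, AUS 75,
#'   ARO 17, ADM 29).
#' @param fst divergence parameter in [0, 1) for training groups.
#' @param holdout_labels group labels treated as distant holdouts.
#' @param holdout_fst_multiplier multiplier on `fst` for holdout groups.
#' @param base_freq_range interval within (0.01, 0.99) for ancestral
#'   allele/presence frequencies.
#' @param marker_counts named integer vector of marker counts per class;
#'   names from `r paste(MARKER_CLASSES, collapse = ", ")`. The default is a
#'   desk-scale panel (2000 SNPs plus 1580 SVs) keeping the relative class
#'   abundances of a genome-wide rice panel.
#' @param linked_pairs list of `list(class=, r2=, count=)` entries
#'   requesting that many SV columns of that class be planted in LD with a
#'   partner SNP at the target r-squared (each target in (0, 1]).
#' @param n_chrom number of chromosomes markers are scattered over.
#' @param seed integer seed; the generator is deterministic given it.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_per_group = c(IND = 451, JAP = 166, AUS = 75,
                                              ARO = 17, ADM = 29),
                              fst = 0.15,
                              holdout_labels = c("ARO", "ADM"),
                              holdout_fst_multiplier = 2,
                              base_freq_range = c(0.05, 0.95),
                              marker_counts = c("SNP" = 2000, "MITE-DTX" = 450,
                                                "RLX-RIX" = 190, "DEL" = 650,
                                                "DUP" = 220, "INV" = 70),
                              linked_pairs = list(),
                              n_chrom = 12L,
                              seed = 1L) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    stop_svgp("n_per_group must be a named vector of group sizes")
  }
  if (any(n_per_group < 0)) stop_svgp("group sizes must be >= 0")
  if (fst < 0 || fst >= 1) stop_svgp("fst must lie in [0, 1)")
  if (fst * holdout_fst_multiplier >= 1) stop_svgp("holdout fst must stay below 1")
  if (base_freq_range[1] <= 0.01 || base_freq_range[2] >= 0.99 ||
      base_freq_range[1] >= base_freq_range[2]) {
    stop_svgp("base_freq_range must be an interval inside (0.01, 0.99)")
  }
  bad <- setdiff(names(marker_counts), MARKER_CLASSES)
  if (length(bad)) stop_svgp("unknown marker class: ", paste(bad, collapse = ", "))
  if (any(marker_counts < 0)) stop_svgp("marker counts must be >= 0")
  for (lp in linked_pairs) {
    if (!all(c("class", "r2", "count") %in% names(lp))) {
      stop_svgp("each linked pair needs class, r2, count")
    }
    if (!lp$class %in% SV_CLASSES) stop_svgp("linked pairs must target an SV class")
    if (lp$r2 <= 0 || lp$r2 > 1) stop_svgp("target r2 must lie in (0, 1]")
    if (lp$count > (marker_counts[lp$class] %||% 0)) {
      stop_svgp("linked pair count exceeds markers of class ", lp$class)
    }
  }
  structure(
    list(n_per_group = n_per_group, fst = fst, holdout_labels = holdout_labels,
         holdout_fst_multiplier = holdout_fst_multiplier,
         base_freq_range = base_freq_range, marker_counts = marker_counts,
         linked_pairs = linked_pairs, n_chrom = as.integer(n_chrom),
         seed = as.integer(seed)),
    class = "population_config"
  )
}

# Flip probability giving expected dosage r2 between a homozygous-coded SNP
# (dosage 2b, b ~ Bernoulli(p)) and its flipped copy; solved by bisection.
# r2(e) = p(1-p)(1-2e)^2 / (q(1-q)), q = p + e - 2pe; decreasing on [0, .5].
flip_rate_for_r2 <- function(p, target_r2) {
  f <- function(e) {
    q <- p + e - 2 * p * e
    p * (1 - p) * (1 - 2 * e)^2 / (q * (1 - q))
  }
  if (target_r2 >= 1) return(0)
  lo <- 0; hi <- 0.5
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) > target_r2) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate a structured multi-group genotype panel
#'
#' Draws SNP dosages (0/1/2) and SV presence/absence (0/1) for every group
#' under Balding-Nichols-perturbed allele frequencies, plants the requested
#' SV-SNP linked pairs, and attaches marker metadata (class, chromosome,
#' position). Partner SNPs of planted pairs are drawn fully homozygous
#' (dosage 0 or 2), mimicking the near-complete homozygosity of a selfing
#' crop, so a target r-squared of 1 is attainable exactly.
#'
#' @param config a [population_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]),
#'   `groups` (label per accession), `linkage` (data.frame of planted
#'   pairs: `sv_id`, `snp_id`, `target_r2`, `realized_r2`), and
#'   `ancestral_freq` (the ancestral allele/presence frequency per marker).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  with_seed(config$seed, {
    groups <- rep(names(config$n_per_group), times = config$n_per_group)
    n <- length(groups)
    if (n == 0L) stop_svgp("empty panel: all group sizes are zero")
    counts <- config$marker_counts[config$marker_counts > 0]
    m <- sum(counts)
    classes <- rep(names(counts), times = counts)
    fst_by_group <- ifelse(names(config$n_per_group) %in% config$holdout_labels,
                           config$fst * config$holdout_fst_multiplier, config$fst)
    names(fst_by_group) <- names(config$n_per_group)

    p_anc <- stats::runif(m, config$base_freq_range[1], config$base_freq_range[2])
    X <- matrix(NA_real_, n, m)
    group_freq <- function(p, F) {
      if (F == 0) return(p)
      stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }
    for (g in names(config$n_per_group)) {
      rows <- which(groups == g)
      if (!length(rows)) next
      pg <- group_freq(p_anc, fst_by_group[[g]])
      pg <- pmin(pmax(pg, 1e-6), 1 - 1e-6)
      for (j in seq_len(m)) {
        X[rows, j] <- if (classes[j] == "SNP") {
          stats::rbinom(length(rows), 2L, pg[j])
        } else {
          stats::rbinom(length(rows), 1L, pg[j])
        }
      }
    }

    ids <- character(m)
    for (cl in names(counts)) {
      idx <- which(classes == cl)
      ids[idx] <- sprintf("%s_%04d", gsub("-", "", cl), seq_along(idx))
    }
    chrom <- sample(config$n_chrom, m, replace = TRUE)
    pos <- sample.int(4e7L, m, replace = TRUE)

    # plant linked SV-SNP pairs
    linkage <- data.frame(sv_id = character(), snp_id = character(),
                          target_r2 = numeric(), realized_r2 = numeric(),
                          stringsAsFactors = FALSE)
    snp_cols <- which(classes == "SNP")
    used_snps <- integer(0)
    used_by_class <- list()
    for (lp in config$linked_pairs) {
      if (!length(snp_cols)) stop_svgp("linked pairs requested but no SNPs simulated")
      sv_cols_all <- which(classes == lp$class)
      taken <- used_by_class[[lp$class]] %||% integer(0)
      sv_cols <- setdiff(sv_cols_all, taken)[seq_len(lp$count)]
      used_by_class[[lp$class]] <- c(taken, sv_cols)
      partners <- sample(setdiff(snp_cols, used_snps), lp$count)
      used_snps <- c(used_snps, partners)
      eps <- NULL
      for (k in seq_len(lp$count)) {
        jsnp <- partners[k]; jsv <- sv_cols[k]
        ok <- FALSE
        for (attempt in 1:50) {
          # redraw the partner SNP fully homozygous at its ancestral frequency
          b <- stats::rbinom(n, 1L, p_anc[jsnp])
          if (length(unique(b)) < 2L) next  # monomorphic draw, retry
          eps <- flip_rate_for_r2(mean(b), lp$r2)
          flip <- stats::rbinom(n, 1L, eps)
          sv <- as.numeric(xor(b, flip))
          if (stats::sd(sv) == 0) next
          r2 <- stats::cor(2 * b, sv)^2
          if (abs(r2 - lp$r2) <= 0.05) {
            X[, jsnp] <- 2 * b
            X[, jsv] <- sv
            chrom[jsv] <- chrom[jsnp]
            pos[jsv] <- pos[jsnp] + 1L
            linkage <- rbind(linkage, data.frame(
              sv_id = ids[jsv], snp_id = ids[jsnp],
              target_r2 = lp$r2, realized_r2 = r2, stringsAsFactors = FALSE))
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop_svgp("could not realize linkage target r2 = ", lp$r2,
                    " (partner effectively monomorphic)")
        }
      }
    }

    markers <- data.frame(id = ids, chrom = as.character(chrom),
                          pos = pos, class = classes, stringsAsFactors = FALSE)
    acc_ids <- sprintf("ACC%04d", seq_len(n))
    list(genotypes = genotype_matrix(X, markers, acc_ids),
         groups = groups, linkage = linkage,
         ancestral_freq = stats::setNames(p_anc, ids))
  })
}

#' Write a simulation ground-truth record as JSON
#'
#' Persists the `truth` component of [simulate_phenotypes()] (causal ids
#' and effects per class, realized variance components, liabilities) so a
#' simulated study can be archived next to its genotype/phenotype files.
#'
#' @param truth the `truth` list returned by [simulate_phenotypes()].
#' @param path output JSON file.
#' @return Invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ground-truth record written by [write_ground_truth()]
#' @param path JSON file.
#' @return The ground-truth list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Specification of a simulated trait
#'
#' @param kind `"quantitative"` or `"binary"`.
#' @param h2 target narrow-sense heritability in [0, 1] (realized exactly on
#'   the simulated sample; see [simulate_phenotypes()]).
#' @param class_variance_shares named vector of genetic-variance shares per
#'   marker class, summing to 1 over classes with causal markers.
#' @param n_causal_per_class causal markers per class (single number or
#'   named vector aligned with `class_variance_shares`).
#' @param dominance_share,epistasis_share nonnegative fractions of the total
#'   genetic variance assigned to dominance (SNP heterozygote deviations)
#'   and additive-by-additive epistasis (pairwise products of causal
#'   dosages); the additive part gets the remainder.
#' @param liability_threshold threshold on the latent liability above which
#'   an accession falls in class 2 (binary traits only).
#' @param seed integer seed.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(kind = c("quantitative", "binary"),
                       h2 = 0.5,
                       class_variance_shares = c("SNP" = 1),
                       n_causal_per_class = 50,
                       dominance_share = 0,
                       epistasis_share = 0,
                       liability_threshold = 0,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (h2 < 0 || h2 > 1) stop_svgp("h2 must lie in [0, 1]")
  shares <- class_variance_shares[class_variance_shares > 0]
  if (abs(sum(shares) - 1) > 1e-9) {
    stop_svgp("class variance shares must sum to 1 (got ", sum(shares), ")")
  }
  bad <- setdiff(names(shares), MARKER_CLASSES)
  if (length(bad)) stop_svgp("unknown class in shares: ", paste(bad, collapse = ", "))
  if (length(n_causal_per_class) == 1L) {
    n_causal_per_class <- stats::setNames(rep(n_causal_per_class, length(shares)),
                                          names(shares))
  }
  if (dominance_share < 0 || epistasis_share < 0 ||
      dominance_share + epistasis_share >= 1) {
    stop_svgp("dominance + epistasis shares must be nonnegative and sum below 1")
  }
  structure(
    list(kind = kind, h2 = h2, class_variance_shares = shares,
         n_causal_per_class = n_causal_per_class[names(shares)],
         dominance_share = dominance_share, epistasis_share = epistasis_share,
         liability_threshold = liability_threshold, seed = as.integer(seed)),
    class = "trait_spec"
  )
}

#' Simulate phenotypes with known genetic architecture
#'
#' Draws Gaussian additive effects per marker class on centered dosages and
#' rescales each class component so its realized sample variance equals the
#' requested share of the (unit) additive genetic variance — realized class
#' shares are therefore exact on the simulated panel. Optional dominance
#' (heterozygote indicator deviations, SNPs only) and additive-by-additive
#' epistasis (products of centered causal dosages) components are rescaled
#' the same way. Environmental noise is orthogonalized against the genetic
#' value and rescaled so the realized sample heritability equals `h2`
#' exactly. Binary traits threshold the latent liability: class 2 above the
#' threshold, class 1 at or below.
#'
#' @param G a [genotype_matrix()] (no missing dosages among causal classes).
#' @param spec a [trait_spec()].
#' @param trait_name column name for the phenotype table.
#' @param groups optional group labels carried into the phenotype table.
#' @return A list: `phenotypes` (a [phenotype_table()]) and `truth`, a list
#'   holding causal ids/effects per class, the genetic values, liabilities,
#'   realized variance components and realized class shares.
#' @export
simulate_phenotypes <- function(G, spec, trait_name = "trait",
                                groups = rep("ALL", length(G$accession_ids))) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(spec, "trait_spec"))
  miss <- setdiff(names(spec$class_variance_shares), unique(G$markers$class))
  if (length(miss)) {
    stop_svgp("classes named in spec absent from genotypes: ",
              paste(miss, collapse = ", "))
  }
  with_seed(spec$seed, {
    n <- nrow(G$dosages)
    scale_to_var <- function(x, v) {
      sx <- stats::sd(x)
      if (sx == 0) stop_svgp("degenerate (constant) genetic component")
      (x - mean(x)) / sx * sqrt(v)
    }
    add_share_total <- 1 - spec$dominance_share - spec$epistasis_share

    g_add <- numeric(n)
    causal <- list()
    realized_shares <- numeric(0)
    for (cl in names(spec$class_variance_shares)) {
      cols <- which(G$markers$class == cl)
      k <- spec$n_causal_per_class[[cl]]
      if (k > length(cols)) {
        stop_svgp("n_causal (", k, ") exceeds markers of class ", cl)
      }
      pick <- sample(cols, k)
      Z <- scale(G$dosages[, pick, drop = FALSE], center = TRUE, scale = FALSE)
      beta <- stats::rnorm(k)
      gc <- drop(Z %*% beta)
      share <- spec$class_variance_shares[[cl]]
      gc_scaled <- scale_to_var(gc, share * add_share_total)
      sf <- sqrt(share * add_share_total) / stats::sd(gc)
      g_add <- g_add + gc_scaled
      causal[[cl]] <- list(ids = G$markers$id[pick], effects = beta * sf)
      realized_shares[cl] <- stats::var(gc_scaled) / add_share_total
    }

    g_dom <- numeric(n)
    if (spec$dominance_share > 0) {
      snp_causal <- causal[["SNP"]]
      if (is.null(snp_causal)) stop_svgp("dominance requires causal SNPs")
      cols <- match(snp_causal$ids, G$markers$id)
      H <- (G$dosages[, cols, drop = FALSE] == 1) * 1
      g_dom <- scale_to_var(drop(H %*% stats::rnorm(length(cols))),
                            spec$dominance_share)
    }
    g_epi <- numeric(n)
    if (spec$epistasis_share > 0) {
      all_causal <- match(unlist(lapply(causal, `[[`, "ids")), G$markers$id)
      if (length(all_causal) < 2L) stop_svgp("epistasis needs >= 2 causal markers")
      n_pairs <- min(length(all_causal), 100L)
      Zc <- scale(G$dosages[, all_causal, drop = FALSE], center = TRUE, scale = FALSE)
      prod_mat <- sapply(seq_len(n_pairs), function(i) {
        jk <- sample(ncol(Zc), 2L)
        Zc[, jk[1]] * Zc[, jk[2]]
      })
      g_epi <- scale_to_var(drop(prod_mat %*% stats::rnorm(n_pairs)),
                            spec$epistasis_share)
    }

    g <- unname(g_add + g_dom + g_epi)
    if (spec$h2 > 0) {
      g_std <- (g - mean(g)) / stats::sd(g)
    } else {
      g_std <- g * 0
    }
    e_raw <- stats::rnorm(n)
    e_orth <- stats::residuals(stats::lm(e_raw ~ g))
    e_std <- (e_orth - mean(e_orth)) / stats::sd(e_orth)
    # latent liability on a scale where Var(genetic) = h2 and Var(env) = 1 - h2
    liab <- sqrt(spec$h2) * g_std + sqrt(1 - spec$h2) * e_std

    if (spec$kind == "quantitative") {
      y <- liab
    } else {
      y <- ifelse(liab > spec$liability_threshold, 2, 1)
      if (length(unique(y)) < 2L) {
        stop_svgp("degenerate binary trait: liability threshold leaves a single class")
      }
    }
    traits <- stats::setNames(data.frame(y), trait_name)
    kinds <- stats::setNames(spec$kind, trait_name)
    pt <- phenotype_table(G$accession_ids, groups, traits, kinds)
    truth <- list(
      causal = causal,
      genetic_values = sqrt(spec$h2) * g_std,
      liabilities = liab,
      realized_h2 = if (spec$h2 > 0) stats::var(sqrt(spec$h2) * g_std) / stats::var(liab) else 0,
      realized_class_shares = realized_shares,
      dominance_share = spec$dominance_share,
      epistasis_share = spec$epistasis_share,
      h2 = spec$h2
    )
    list(phenotypes = pt, truth = truth)
  })
}
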