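# Genotype-level pedigree simulator: founder haplotypes, Poisson-crossover
# meioses on a constant-rate genetic map, age-dependent DNMs with optional
# mutator inflation, gene conversion, genotype error, allele-depth sampling,
# and full truth records (planted DNMs, breakpoints, true IBD segments).

#' Default simulation-truth parental-age coefficients
#'
#' Documented synthetic coefficients used as the simulator's ground truth:
#' at parental ages (28, 32) they yield about 70 DNMs per child, roughly 75%
#' of paternal origin, with a spectrum of C>T 38%, A>G 26%, C>A 10%, C>G 9%,
#' A>T 9%, A>C 8% — the broad shape of the human germline spectrum. The
#' reference genome size equals the default [genome_layout()] (2 x 100 Mb),
#' so the accessibility scale is 1 in default simulations. These are the
#' package's own values for benchmarking, not an external model fit.
#'
#' @return A `kin_coeffs`.
#' @export
default_age_coefficients <- function() {
  shares <- c("C>A" = 0.10, "C>G" = 0.09, "C>T" = 0.38,
              "A>C" = 0.08, "A>G" = 0.26, "A>T" = 0.09)
  # maternal total: 0.40/yr slope + 6.3 intercept -> 17.5 at age 28 (25%)
  # paternal total: 1.40/yr slope + 7.7 intercept -> 52.5 at age 32 (75%)
  age_coefficients(
    tibble(
      type = names(shares),
      m_mat = 0.40 * shares, b_mat = 6.3 * shares,
      m_pat = 1.40 * shares, b_pat = 7.7 * shares
    ),
    reference_genome_bp = 2e8
  )
}

#' Simulation configuration
#'
#' @param layout Genome layout (see [genome_layout()]).
#' @param n_children Number of full siblings to simulate.
#' @param a_mat,a_pat Parental ages (years) at each child's conception.
#' @param coefficients Truth `kin_coeffs` driving per-type DNM counts.
#' @param mutator List: `target` (`"none"`, `"maternal"`, `"paternal"` or
#'   `"embryonic"`), `type` (a mutation class) and `fold` (>= 1). Maternal /
#'   paternal targets multiply that parent's expected count of the targeted
#'   type; the embryonic target deposits extra unphased mutations
#'   post-zygotically at `(fold - 1)` times the type's total expectation.
#' @param marker_density Expected segregating markers per bp.
#' @param founder_freq Function `n -> n` alternate-allele frequencies for
#'   founder markers (default `rbeta(n, 0.5, 0.5)`, a U-shaped frequency
#'   spectrum rich in common variants).
#' @param depth_mean Mean sequencing depth for allele-depth sampling.
#' @param genotype_error_rate Per-haplotype, per-site allele flip rate.
#' @param gene_conversion List: `rate` (expected tracts per meiosis) and
#'   `tract_length_bp`.
#' @return A `kin_sim_config` list.
#' @export
sim_config <- function(layout = genome_layout(), n_children = 5,
                       a_mat = 28, a_pat = 32,
                       coefficients = default_age_coefficients(),
                       mutator = list(target = "none", type = "C>A", fold = 1),
                       marker_density = 1e-3,
                       founder_freq = function(n) rbeta(n, 0.5, 0.5),
                       depth_mean = 50, genotype_error_rate = 0,
                       gene_conversion = list(rate = 0, tract_length_bp = 1000)) {
  stopifnot(n_children >= 1, a_mat > 0, a_pat > 0, marker_density > 0,
            depth_mean > 0, genotype_error_rate >= 0,
            gene_conversion$rate >= 0)
  mutator$target <- match.arg(mutator$target,
                              c("none", "maternal", "paternal", "embryonic"))
  if (mutator$target != "none") {
    stopifnot(mutator$type %in% MUTATION_TYPES)
    if (mutator$fold < 1) abort("mutator fold must be >= 1")
  }
  structure(
    list(layout = layout, n_children = n_children, a_mat = a_mat,
         a_pat = a_pat, coefficients = coefficients, mutator = mutator,
         marker_density = marker_density, founder_freq = founder_freq,
         depth_mean = depth_mean, genotype_error_rate = genotype_error_rate,
         gene_conversion = gene_conversion),
    class = "kin_sim_config"
  )
}

#' Simulate two unrelated founder genomes
#'
#' Marker count per chromosome is Poisson in `marker_density x length`;
#' positions are uniform, alternate frequencies come from the configured
#' founder frequency spectrum, and the four founder haplotypes draw alleles
#' independently at those frequencies (founders unrelated by construction).
#'
#' @param config A `kin_sim_config`.
#' @return A `kin_geno` with individuals `"mother"` and `"father"`.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "kin_sim_config"))
  bases <- c("A", "C", "G", "T")
  site_list <- map(seq_len(nrow(config$layout)), function(i) {
    len <- config$layout$length_bp[i]
    n <- rpois(1, config$marker_density * len)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(len, n)) - 1
    ref <- sample(bases, n, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1 + sample(3, n, replace = TRUE)) %% 4 + 1]
    tibble(chrom = config$layout$chrom[i], pos = as.double(pos),
           ref = ref, alt = alt, panel_af = config$founder_freq(n))
  })
  sites <- bind_rows(site_list)
  if (is.null(sites) || nrow(sites) == 0) abort("zero markers simulated; increase marker_density")
  n <- nrow(sites)
  draw <- function() rbinom(n, 1, sites$panel_af)
  hap1 <- cbind(mother = draw(), father = draw())
  hap2 <- cbind(mother = draw(), father = draw())
  genotype_matrix(sites, hap1, hap2)
}

# Crossover breakpoints for one meiosis: count per chromosome is Poisson in
# the genetic length (Morgans), positions uniform; plus a random start hap.
meiosis_breakpoints <- function(layout) {
  bk <- map(seq_len(nrow(layout)), function(i) {
    morgans <- layout$length_bp[i] * layout$cm_per_mb[i] * 1e-6 / 100
    n <- rpois(1, morgans)
    if (n == 0) return(NULL)
    tibble(chrom = layout$chrom[i],
           pos = sort(runif(n, 0, layout$length_bp[i])))
  })
  bk <- bind_rows(bk)
  if (nrow(bk) == 0) bk <- tibble(chrom = character(), pos = double())
  list(
    breakpoints = bk,
    start_hap = setNames(sample(1:2, nrow(layout), replace = TRUE),
                         layout$chrom)
  )
}

# Source haplotype (1/2) of a gamete at arbitrary positions on one chromosome.
source_at <- function(pos, bkpos, start_hap) {
  k <- findInterval(pos, bkpos)
  ifelse(k %% 2 == 0, start_hap, 3L - start_hap)
}

# Source intervals (chrom, start, end, source) for a whole meiosis.
source_intervals <- function(meiosis, layout) {
  map_dfr(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    len <- layout$length_bp[i]
    bkpos <- meiosis$breakpoints$pos[meiosis$breakpoints$chrom == ch]
    bounds <- c(0, bkpos, len)
    src <- source_at((head(bounds, -1) + tail(bounds, -1)) / 2, bkpos,
                     meiosis$start_hap[[ch]])
    tibble(chrom = ch, start = head(bounds, -1), end = tail(bounds, -1),
           source = as.integer(src))
  })
}

#' Simulate one meiosis of a phased parent
#'
#' Crossover counts per chromosome are Poisson in the chromosome's genetic
#' length; the gamete alternates between the parent's two haplotypes at the
#' sampled breakpoints, independently across chromosomes.
#'
#' @param geno A `kin_geno` containing the parent.
#' @param parent Parent id.
#' @param layout Genome layout.
#' @return A list: `alleles` (gamete allele vector over `geno$sites`),
#'   `breakpoints` (tibble `chrom`, `pos`), `source` (source-haplotype
#'   interval tibble).
#' @export
simulate_meiosis <- function(geno, parent, layout) {
  geno_check_sample(geno, parent)
  m <- meiosis_breakpoints(layout)
  src_iv <- source_intervals(m, layout)
  alleles <- rep(NA_integer_, nrow(geno$sites))
  for (ch in unique(geno$sites$chrom)) {
    idx <- geno_chrom_idx(geno, ch)
    bkpos <- m$breakpoints$pos[m$breakpoints$chrom == ch]
    src <- source_at(geno$sites$pos[idx], bkpos, m$start_hap[[ch]])
    alleles[idx] <- ifelse(src == 1L, geno$hap1[idx, parent],
                           geno$hap2[idx, parent])
  }
  list(alleles = alleles, breakpoints = m$breakpoints,
       start_hap = m$start_hap, source = src_iv)
}

# Overlay gene-conversion tracts: within each tract the gamete copies the
# homologous (non-source) parental haplotype.
apply_gene_conversion <- function(alleles, meiosis, geno, parent, layout,
                                  rate, tract_length_bp) {
  tracts <- iv_empty()
  if (rate > 0) {
    tr <- map_dfr(seq_len(nrow(layout)), function(i) {
      n <- rpois(1, rate)
      if (n == 0) return(NULL)
      start <- runif(n, 0, max(1, layout$length_bp[i] - tract_length_bp))
      tibble(chrom = layout$chrom[i], start = floor(start),
             end = floor(start) + tract_length_bp)
    })
    if (nrow(tr) > 0) {
      tracts <- tr
      for (k in seq_len(nrow(tr))) {
        ch <- tr$chrom[k]
        idx <- geno_chrom_idx(geno, ch)
        hit <- idx[geno$sites$pos[idx] >= tr$start[k] &
                     geno$sites$pos[idx] < tr$end[k]]
        if (length(hit) == 0) next
        bkpos <- meiosis$breakpoints$pos[meiosis$breakpoints$chrom == ch]
        src <- source_at(geno$sites$pos[hit], bkpos, meiosis$start_hap[[ch]])
        other <- 3L - src
        alleles[hit] <- ifelse(other == 1L, geno$hap1[hit, parent],
                               geno$hap2[hit, parent])
      }
    }
  }
  list(alleles = alleles, tracts = tracts)
}

# Draw a (ref, alt) pair realising a 1-mer class on a random strand.
type_to_alleles <- function(type) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r <- substr(type, 1, 1)
  a <- substr(type, 3, 3)
  if (runif(1) < 0.5) c(r, a) else unname(c(comp[r], comp[a]))
}

#' Simulate a complete nuclear family with truth records
#'
#' Children are paired meioses of two simulated founders. Per-child DNM
#' counts per type and parent of origin are Poisson in the truth
#' parental-age model (scaled to the simulated genome size), with the
#' configured mutator fold applied; DNMs are placed uniformly at
#' non-segregating positions on the corresponding haplotype (haplotype 1 is
#' maternal by construction). Gene conversion, genotype error and allele
#' depths are overlaid as configured.
#'
#' @param config A `kin_sim_config`.
#' @return A list with elements `geno` (`kin_geno` for mother, father and
#'   children `C1..Cn`), `pedigree` (`kin_pedigree`) and `truth` (list:
#'   `dnms`, `meioses` (per child, maternal/paternal source intervals and
#'   breakpoints), `conversion_tracts`, `genotype_errors`, `expected`
#'   (per-child truth expectation incl. mutator), `config`).
#' @export
simulate_family <- function(config) {
  stopifnot(inherits(config, "kin_sim_config"))
  founders <- simulate_founders(config)
  layout <- config$layout
  scale <- min(1, layout_total_bp(layout) /
                 attr(config$coefficients, "reference_genome_bp"))
  expectation <- expected_counts(config$coefficients, config$a_mat,
                                 config$a_pat, scale)
  mut <- config$mutator
  exp_mat <- setNames(expectation$expected_mat, expectation$type)
  exp_pat <- setNames(expectation$expected_pat, expectation$type)
  exp_emb <- setNames(rep(0, 6), expectation$type)
  if (mut$target == "maternal") {
    exp_mat[mut$type] <- exp_mat[mut$type] * mut$fold
  } else if (mut$target == "paternal") {
    exp_pat[mut$type] <- exp_pat[mut$type] * mut$fold
  } else if (mut$target == "embryonic") {
    exp_emb[mut$type] <- (mut$fold - 1) *
      (exp_mat[mut$type] + exp_pat[mut$type])
  }

  children <- paste0("C", seq_len(config$n_children))
  meioses <- list()
  gametes_mat <- list()
  gametes_pat <- list()
  tracts_all <- list()
  for (ch_id in children) {
    mm <- simulate_meiosis(founders, "mother", layout)
    mp <- simulate_meiosis(founders, "father", layout)
    gcm <- apply_gene_conversion(mm$alleles, mm, founders, "mother", layout,
                                 config$gene_conversion$rate,
                                 config$gene_conversion$tract_length_bp)
    gcp <- apply_gene_conversion(mp$alleles, mp, founders, "father", layout,
                                 config$gene_conversion$rate,
                                 config$gene_conversion$tract_length_bp)
    gametes_mat[[ch_id]] <- gcm$alleles
    gametes_pat[[ch_id]] <- gcp$alleles
    if (nrow(gcm$tracts) > 0) {
      tracts_all[[length(tracts_all) + 1]] <-
        mutate(gcm$tracts, child = ch_id, parent = "mother")
    }
    if (nrow(gcp$tracts) > 0) {
      tracts_all[[length(tracts_all) + 1]] <-
        mutate(gcp$tracts, child = ch_id, parent = "father")
    }
    meioses[[ch_id]] <- list(
      maternal = list(breakpoints = mm$breakpoints, source = mm$source),
      paternal = list(breakpoints = mp$breakpoints, source = mp$source)
    )
  }

  # plant DNMs at fresh non-segregating positions
  used <- unique(paste(founders$sites$chrom, founders$sites$pos))
  dnm_rows <- list()
  for (ch_id in children) {
    for (ty in MUTATION_TYPES) {
      for (origin in c("maternal", "paternal", "embryonic")) {
        lambda <- switch(origin, maternal = exp_mat[[ty]],
                         paternal = exp_pat[[ty]], embryonic = exp_emb[[ty]])
        n <- if (lambda > 0) rpois(1, lambda) else 0
        if (n == 0) next
        for (k in seq_len(n)) {
          repeat {
            ci <- sample.int(nrow(layout), 1, prob = layout$length_bp)
            p <- as.double(sample.int(layout$length_bp[ci], 1) - 1)
            key <- paste(layout$chrom[ci], p)
            if (!key %in% used) { used <- c(used, key); break }
          }
          ra <- type_to_alleles(ty)
          hap <- switch(origin, maternal = 1L, paternal = 2L,
                        embryonic = sample(1:2, 1))
          dnm_rows[[length(dnm_rows) + 1]] <- tibble(
            child = ch_id, chrom = layout$chrom[ci], pos = p,
            ref = ra[1], alt = ra[2], type = ty,
            parent_of_origin = origin, hap = hap
          )
        }
      }
    }
  }
  dnms <- if (length(dnm_rows) > 0) {
    bind_rows(dnm_rows)
  } else {
    tibble(child = character(), chrom = character(), pos = double(),
           ref = character(), alt = character(), type = character(),
           parent_of_origin = character(), hap = integer())
  }

  # assemble the family's site table: founder markers + DNM sites
  dnm_sites <- if (nrow(dnms) > 0) {
    distinct(tibble(chrom = dnms$chrom, pos = dnms$pos, ref = dnms$ref,
                    alt = dnms$alt, panel_af = 0))
  } else {
    tibble(chrom = character(), pos = double(), ref = character(),
           alt = character(), panel_af = double())
  }
  sites <- bind_rows(founders$sites, dnm_sites)
  ord <- order(factor(sites$chrom, levels = layout$chrom), sites$pos)
  sites <- sites[ord, ]
  n_sites <- nrow(sites)
  n_founder <- nrow(founders$sites)
  founder_rows <- match(
    paste(founders$sites$chrom, founders$sites$pos),
    paste(sites$chrom, sites$pos)
  )

  ids <- c("mother", "father", children)
  hap1 <- matrix(0L, n_sites, length(ids), dimnames = list(NULL, ids))
  hap2 <- hap1
  hap1[founder_rows, "mother"] <- founders$hap1[, "mother"]
  hap2[founder_rows, "mother"] <- founders$hap2[, "mother"]
  hap1[founder_rows, "father"] <- founders$hap1[, "father"]
  hap2[founder_rows, "father"] <- founders$hap2[, "father"]
  for (ch_id in children) {
    hap1[founder_rows, ch_id] <- gametes_mat[[ch_id]]
    hap2[founder_rows, ch_id] <- gametes_pat[[ch_id]]
  }
  if (nrow(dnms) > 0) {
    dnm_rows_idx <- match(paste(dnms$chrom, dnms$pos), paste(sites$chrom, sites$pos))
    for (k in seq_len(nrow(dnms))) {
      if (dnms$hap[k] == 1L) {
        hap1[dnm_rows_idx[k], dnms$child[k]] <- 1L
      } else {
        hap2[dnm_rows_idx[k], dnms$child[k]] <- 1L
      }
    }
  }

  # genotype error: per-haplotype allele flips on the observed matrices
  flips <- tibble(individual = character(), chrom = character(),
                  pos = double(), hap = integer())
  if (config$genotype_error_rate > 0) {
    for (id in ids) {
      for (h in 1:2) {
        m <- if (h == 1) hap1 else hap2
        flip <- runif(n_sites) < config$genotype_error_rate
        if (any(flip)) {
          m[flip, id] <- 1L - m[flip, id]
          if (h == 1) hap1 <- m else hap2 <- m
          flips <- bind_rows(flips, tibble(
            individual = id, chrom = sites$chrom[flip],
            pos = sites$pos[flip], hap = h
          ))
        }
      }
    }
  }

  # allele depths: depth ~ Poisson(mean), alt reads ~ Binomial(depth, dosage/2)
  depth <- matrix(rpois(n_sites * length(ids), config$depth_mean),
                  n_sites, length(ids), dimnames = list(NULL, ids))
  dos <- hap1 + hap2
  ad_alt <- matrix(rbinom(n_sites * length(ids), as.vector(depth),
                          as.vector(dos) / 2),
                   n_sites, length(ids), dimnames = list(NULL, ids))
  ad_ref <- depth - ad_alt

  geno <- genotype_matrix(sites, hap1, hap2, ad_ref = ad_ref, ad_alt = ad_alt)
  ped <- pedigree(tibble(
    id = ids,
    sex = c("female", "male", rep("unknown", length(children))),
    mother_id = c(NA, NA, rep("mother", length(children))),
    father_id = c(NA, NA, rep("father", length(children)))
  ))
  conv <- if (length(tracts_all) > 0) {
    bind_rows(tracts_all)
  } else {
    tibble(chrom = character(), start = double(), end = double(),
           child = character(), parent = character())
  }
  truth <- list(
    dnms = dnms,
    meioses = meioses,
    conversion_tracts = conv,
    genotype_errors = flips,
    expected = list(maternal = exp_mat, paternal = exp_pat,
                    embryonic = exp_emb),
    config = config
  )
  list(geno = geno, pedigree = ped, truth = truth)
}

# Intervals where two source-interval tibbles agree (same source haplotype).
src_equal_intervals <- function(src_a, src_b, layout) {
  out <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    ch <- layout$chrom[i]
    sel_a <- src_a$chrom == ch
    sel_b <- src_b$chrom == ch
    cuts <- sort(unique(c(src_a$start[sel_a], src_a$end[sel_a],
                          src_b$start[sel_b], src_b$end[sel_b])))
    if (length(cuts) < 2) next
    lo <- cuts[-length(cuts)]; hi <- cuts[-1]
    mid <- (lo + hi) / 2
    sa <- src_a$source[sel_a][findInterval(mid, src_a$start[sel_a])]
    sb <- src_b$source[sel_b][findInterval(mid, src_b$start[sel_b])]
    eq <- sa == sb
    if (!any(eq)) next
    # merge adjacent equal elementary intervals
    r <- rle(eq)
    j <- cumsum(r$lengths)
    s <- j - r$lengths + 1
    out[[i]] <- tibble(chrom = ch, start = lo[s[r$values]],
                       end = hi[j[r$values]])
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) iv_empty() else res
}

#' True IBD segments between simulated siblings
#'
#' Derived directly from the recorded meiosis source intervals: per parent,
#' the intervals where both siblings inherited the same parental haplotype,
#' labelled `"maternal"` / `"paternal"` (haplotype 1 is maternal and 2 is
#' paternal for every simulated child).
#'
#' @param truth Truth record from [simulate_family()].
#' @param pair Two child ids; default all sibling pairs.
#' @return A classified segment tibble (with `n_markers = NA`).
#' @export
true_ibd_segments <- function(truth, pair = NULL) {
  layout <- truth$config$layout
  children <- names(truth$meioses)
  pairs <- if (is.null(pair)) {
    if (length(children) < 2) return(empty_segments())
    utils::combn(children, 2, simplify = FALSE)
  } else {
    list(pair)
  }
  map_dfr(pairs, function(pr) {
    out <- list()
    for (side in c("maternal", "paternal")) {
      shared <- src_equal_intervals(
        truth$meioses[[pr[1]]][[side]]$source,
        truth$meioses[[pr[2]]][[side]]$source,
        layout
      )
      if (nrow(shared) == 0) next
      h <- if (side == "maternal") 1L else 2L
      out[[side]] <- tibble(
        id_a = pr[1], hap_a = h, id_b = pr[2], hap_b = h,
        chrom = shared$chrom, start = shared$start, end = shared$end,
        n_markers = NA_integer_, origin = side
      )
    }
    bind_rows(out)
  })
}

#' Monte-Carlo sibling haplotype-sharing fractions
#'
#' Simulates pairs of full siblings (four meioses each) and reports, per
#' pair, the fraction of the genome where they share the maternal haplotype,
#' the paternal haplotype, and both at once (the double-surrogate geometry).
#' Operates on recombination breakpoints only — no markers are needed.
#'
#' @param n_pairs Number of sibling pairs.
#' @param layout Genome layout.
#' @return Tibble with `frac_maternal`, `frac_paternal`, `frac_both` per pair.
#' @export
sibling_sharing <- function(n_pairs, layout = genome_layout()) {
  genome <- layout_total_bp(layout)
  morgans <- layout$length_bp * layout$cm_per_mb * 1e-6 / 100
  # lean per-chromosome path: four meioses as (breakpoints, start hap), shared
  # lengths summed over the elementary intervals their breakpoints induce
  one_meiosis <- function(i) {
    n <- rpois(1, morgans[i])
    list(bk = if (n > 0) sort(runif(n, 0, layout$length_bp[i])) else numeric(),
         s = sample(1:2, 1))
  }
  res <- matrix(0, n_pairs, 3)
  for (p in seq_len(n_pairs)) {
    shared_mat <- shared_pat <- shared_both <- 0
    for (i in seq_len(nrow(layout))) {
      m1 <- one_meiosis(i); m2 <- one_meiosis(i)
      f1 <- one_meiosis(i); f2 <- one_meiosis(i)
      cuts <- sort(unique(c(0, m1$bk, m2$bk, f1$bk, f2$bk, layout$length_bp[i])))
      lo <- cuts[-length(cuts)]; hi <- cuts[-1]
      mid <- (lo + hi) / 2
      w <- hi - lo
      eq_m <- source_at(mid, m1$bk, m1$s) == source_at(mid, m2$bk, m2$s)
      eq_p <- source_at(mid, f1$bk, f1$s) == source_at(mid, f2$bk, f2$s)
      shared_mat <- shared_mat + sum(w[eq_m])
      shared_pat <- shared_pat + sum(w[eq_p])
      shared_both <- shared_both + sum(w[eq_m & eq_p])
    }
    res[p, ] <- c(shared_mat, shared_pat, shared_both) / genome
  }
  tibble(frac_maternal = res[, 1], frac_paternal = res[, 2],
         frac_both = res[, 3])
}

#' Simulate true sibling IBD segments without genotypes
#'
#' Breakpoint-level simulation of one sibship: each child is a pair of
#' meioses, and true IBD segments between every sibling pair are derived from
#' the source intervals, labelled maternal/paternal. Much faster than
#' [simulate_family()] when only the sharing geometry matters (callable
#' fraction studies).
#'
#' @param n_children Number of siblings (children are `"C1"`, `"C2"`, ...).
#' @param layout Genome layout.
#' @param proband Restrict the output to pairs involving this child
#'   (`NULL` = all sibling pairs).
#' @return A classified segment tibble.
#' @export
simulate_ibd_truth <- function(n_children, layout = genome_layout(),
                               proband = NULL) {
  children <- paste0("C", seq_len(n_children))
  meioses <- map(children, function(ch) {
    list(
      maternal = list(source = source_intervals(meiosis_breakpoints(layout), layout)),
      paternal = list(source = source_intervals(meiosis_breakpoints(layout), layout))
    )
  })
  names(meioses) <- children
  truth <- list(meioses = meioses, config = list(layout = layout))
  if (is.null(proband)) return(true_ibd_segments(truth))
  others <- setdiff(children, proband)
  bind_rows(map(others, ~ true_ibd_segments(truth, c(proband, .x))))
}

#' Benchmark DNM calls against simulation truth
#'
#' @param calls A filtered `kin_calls` for one simulated proband.
#' @param truth Truth record from [simulate_family()].
#' @param regions The `kin_regions` used for calling.
#' @param boundary_margin_bp Distance from a true recombination breakpoint
#'   within which a false positive is attributed to IBD-boundary effects.
#' @return A list: `precision`, `recall`, `recall_in_accessible`, counts
#'   (`tp`, `fp`, `fn`), `fn_by_cause` (inaccessible / sib_shared / filtered
#'   / missed) and `fp_by_cause` (gene_conversion / genotype_error /
#'   ibd_boundary / other).
#' @export
benchmark_calls <- function(calls, truth, regions, boundary_margin_bp = 1e5) {
  stopifnot(inherits(regions, "kin_regions"))
  proband <- regions$proband
  if (nrow(calls) > 0 && !all(calls$proband == proband)) {
    abort("calls and regions refer to different probands")
  }
  planted <- truth$dnms[truth$dnms$child == proband, ]
  key <- function(ch, p) paste(ch, p)
  pass <- calls[calls$pass %in% TRUE, ]
  tp_keys <- intersect(key(pass$chrom, pass$pos), key(planted$chrom, planted$pos))
  tp <- length(tp_keys)
  fp <- pass[!key(pass$chrom, pass$pos) %in% tp_keys, ]

  # false-negative partition
  missed <- planted[!key(planted$chrom, planted$pos) %in% tp_keys, ]
  in_acc <- iv_contains(regions$regions, missed$chrom, missed$pos)
  sib_dnms <- truth$dnms[truth$dnms$child != proband, ]
  sib_shared <- key(missed$chrom, missed$pos) %in% key(sib_dnms$chrom, sib_dnms$pos)
  was_called <- key(missed$chrom, missed$pos) %in% key(calls$chrom, calls$pos)
  fn_by_cause <- c(
    inaccessible = sum(!in_acc),
    sib_shared = sum(in_acc & sib_shared),
    filtered = sum(in_acc & !sib_shared & was_called),
    missed = sum(in_acc & !sib_shared & !was_called)
  )

  # false-positive attribution
  tr <- truth$conversion_tracts
  in_conv <- if (nrow(tr) > 0) {
    iv_contains(tr[, c("chrom", "start", "end")], fp$chrom, fp$pos)
  } else rep(FALSE, nrow(fp))
  ge <- truth$genotype_errors
  is_err <- key(fp$chrom, fp$pos) %in% key(ge$chrom, ge$pos)
  bk <- map_dfr(truth$meioses, function(m) {
    bind_rows(m$maternal$breakpoints, m$paternal$breakpoints)
  })
  near_bk <- map_dbl(seq_len(nrow(fp)), function(k) {
    b <- bk$pos[bk$chrom == fp$chrom[k]]
    if (length(b) == 0) return(Inf)
    min(abs(b - fp$pos[k]))
  }) <= boundary_margin_bp
  fp_by_cause <- c(
    gene_conversion = sum(in_conv),
    genotype_error = sum(!in_conv & is_err),
    ibd_boundary = sum(!in_conv & !is_err & near_bk),
    other = sum(!in_conv & !is_err & !near_bk)
  )

  accessible_planted <- sum(iv_contains(regions$regions, planted$chrom, planted$pos))
  list(
    precision = if (tp + nrow(fp) > 0) tp / (tp + nrow(fp)) else NA_real_,
    recall = if (nrow(planted) > 0) tp / nrow(planted) else NA_real_,
    recall_in_accessible = if (accessible_planted > 0) tp / accessible_planted else NA_real_,
    tp = tp, fp = nrow(fp), fn = nrow(missed),
    fn_by_cause = fn_by_cause,
    fp_by_cause = fp_by_cause
  )
}
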