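# Synthetic ocean-community generator with planted ground truth.
#
# Emulates the structure of the field study: a long-tailed (lognormal)
# rank-abundance community observed across depth layers and plankton size
# fractions, a culture collection drawn from a culturable subset whose
# read share rises with depth and particle size, isolate sequences that
# contain their source ASV region verbatim between concrete primer sites,
# rRNA-operon copy-number-inflated read counts, and per-station cfu/cell
# pairs. Every planted quantity is recorded so downstream statistics can
# be checked against known truth.

.concretize_primer <- function(primer) {
  # first base of each IUPAC expansion; a valid realization of the site
  first <- c(A = "A", C = "C", G = "G", T = "T", R = "A", Y = "C", S = "C",
             W = "A", K = "G", M = "A", B = "C", D = "A", H = "A", V = "A",
             N = "A")
  paste(first[strsplit(primer, "", fixed = TRUE)[[1L]]], collapse = "")
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

#' Configuration for a synthetic study
#'
#' Defaults describe a down-scaled but structurally faithful ocean study:
#' 300 taxa with lognormal rank abundance (sdlog 2 gives a few taxa above
#' 1\% and a long rare tail), four depth layers by two size fractions with
#' 5 samples each at 50 000 reads, a 373 nt region (the V4-V5 span between
#' the default primers), planted culturable read fractions rising from the
#' surface (3\%) to the bathypelagic (28\%) and boosted 1.4x on particles,
#' copy-number inflation only in the culturable subset (lognormal, median
#' 3.5 operons), and 11\% of isolates mutated so they cannot match.
#'
#' @param n_taxa Number of ASVs (>= 10).
#' @param meanlog,sdlog Lognormal rank-abundance shape.
#' @param layers Depth layers used (subset of SRF/DCM/MESO/BATHY).
#' @param size_fractions Plankton size fractions (um labels).
#' @param n_samples_per_stratum Samples per (layer, size fraction).
#' @param reads_per_sample Target reads per sample.
#' @param reads_jitter Relative uniform jitter on sample depth.
#' @param region_length ASV region length in nt.
#' @param culturable_read_fraction Named per-layer planted read fraction of
#'   the culturable subset (free-living fraction).
#' @param attached_boost Multiplier on the planted fraction for
#'   particle-attached size fractions (capped at 0.9).
#' @param n_culturable Number of culturable taxa.
#' @param copiotroph_bias Exponent beta: isolate sampling probability
#'   proportional to abundance^beta.
#' @param copy_number_model "inflated" (culturable genera lognormal with
#'   median \code{copy_median}, others 1) or "none" (all 1).
#' @param copy_median,copy_sdlog Copy-number distribution of culturable
#'   genera under the inflated model.
#' @param isolate_count Total isolates in the collection.
#' @param nonmatch_fraction Fraction of isolates given a substitution
#'   inside the region so they cannot match.
#' @param ensure_coverage Guarantee at least one isolate per culturable
#'   taxon (the collection inventories the culturable subset), remaining
#'   quota drawn with the copiotroph bias.
#' @param arch_frac,cyano_frac Fractions of taxa labelled Archaea /
#'   Cyanobacteria (never culturable; exercise the taxon filter).
#' @param n_stations Stations for isolate metadata, split over layers.
#' @param seed Mandatory master seed.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(n_taxa = 300L,
                       meanlog = 0, sdlog = 2,
                       layers = c("SRF", "DCM", "MESO", "BATHY"),
                       size_fractions = c("0.2-0.8", "0.8-20"),
                       n_samples_per_stratum = 5L,
                       reads_per_sample = 50000L,
                       reads_jitter = 0.05,
                       region_length = 373L,
                       culturable_read_fraction = c(SRF = 0.03, DCM = 0.02,
                                                    MESO = 0.085, BATHY = 0.28),
                       attached_boost = 1.4,
                       n_culturable = 25L,
                       copiotroph_bias = 1,
                       copy_number_model = c("inflated", "none"),
                       copy_median = 3.5, copy_sdlog = 0.25,
                       isolate_count = 200L,
                       nonmatch_fraction = 0.11,
                       ensure_coverage = TRUE,
                       arch_frac = 0.05, cyano_frac = 0.05,
                       n_stations = 23L,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  copy_number_model <- match.arg(copy_number_model)
  stopifnot(n_taxa >= 10L, sdlog >= 0, region_length >= 50L,
            all(layers %in% SAMPLE_LAYERS),
            all(size_fractions %in% SIZE_FRACTIONS),
            all(layers %in% names(culturable_read_fraction)),
            n_culturable >= 1L, n_culturable <= n_taxa,
            isolate_count >= 1L, n_stations >= length(layers))
  fr <- c(culturable_read_fraction, nonmatch_fraction, arch_frac, cyano_frac,
          reads_jitter)
  stopifnot(all(fr >= 0 & fr <= 1))
  structure(list(
    n_taxa = as.integer(n_taxa), meanlog = meanlog, sdlog = sdlog,
    layers = layers, size_fractions = size_fractions,
    n_samples_per_stratum = as.integer(n_samples_per_stratum),
    reads_per_sample = as.integer(reads_per_sample),
    reads_jitter = reads_jitter,
    region_length = as.integer(region_length),
    culturable_read_fraction = culturable_read_fraction,
    attached_boost = attached_boost,
    n_culturable = as.integer(n_culturable),
    copiotroph_bias = copiotroph_bias,
    copy_number_model = copy_number_model,
    copy_median = copy_median, copy_sdlog = copy_sdlog,
    isolate_count = as.integer(isolate_count),
    nonmatch_fraction = nonmatch_fraction,
    ensure_coverage = isTRUE(ensure_coverage),
    arch_frac = arch_frac, cyano_frac = cyano_frac,
    n_stations = as.integer(n_stations),
    seed = as.integer(seed)), class = "sim_config")
}

.strata_of <- function(config) {
  g <- expand.grid(layer = config$layers,
                   size_fraction = config$size_fractions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$stratum <- paste(g$layer, g$size_fraction, sep = "|")
  g$f_planted <- pmin(0.9, config$culturable_read_fraction[g$layer] *
                        ifelse(g$size_fraction == "0.2-0.8", 1,
                               config$attached_boost))
  g
}

#' Simulate the ASV community
#'
#' Draws lognormal taxon abundances, assigns synthetic taxonomy (with
#' Archaea and Cyanobacteria fractions), generates pairwise-distinct random
#' ASV sequences of the region length, picks the culturable taxon subset
#' (heterotrophic bacteria only, sampled with a mild abundance bias) and
#' rescales each stratum's abundance vector so the culturable subset holds
#' exactly its planted read fraction. Copy numbers are assigned per genus.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: asv_seqs, taxonomy, copy_numbers (data.frame), abundance
#'   (strata x taxa matrix, rows sum to 1), strata (data.frame), culturable
#'   (ASV ids), truth.
#' @export
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_taxa
  ids <- sprintf("ASV_%04d", seq_len(n))

  # taxonomy: first carve out Archaea and Cyanobacteria, rest heterotrophs
  n_arch <- round(config$arch_frac * n)
  n_cyano <- round(config$cyano_frac * n)
  roles <- rep("het", n)
  roles[sample.int(n, n_arch + n_cyano)] <- c(rep("arch", n_arch),
                                              rep("cyano", n_cyano))
  phyla <- c("Proteobacteria", "Bacteroidetes", "Actinobacteria", "Firmicutes")
  genus <- sprintf("Genus_%04d", seq_len(n))
  taxonomy <- character(n)
  for (i in seq_len(n)) {
    taxonomy[i] <- switch(roles[i],
      arch = paste("Archaea", "Crenarchaeota", "Nitrososphaeria", "",
                   "", genus[i], sep = ";"),
      cyano = paste("Bacteria", "Cyanobacteria", "Cyanobacteriia", "",
                    "", genus[i], sep = ";"),
      het = paste("Bacteria", sample(phyla, 1L), "", "", "", genus[i],
                  sep = ";"))
  }
  names(taxonomy) <- ids

  # distinct random sequences; collisions astronomically unlikely at 373 nt
  seqs <- .random_dna(n, config$region_length)
  tries <- 0L
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- .random_dna(length(dup), config$region_length)
    tries <- tries + 1L
    if (tries > 100L) stop("could not generate distinct ASV sequences")
  }
  names(seqs) <- ids

  base <- stats::rlnorm(n, config$meanlog, config$sdlog)
  het <- which(roles == "het")
  if (length(het) < config$n_culturable) {
    stop("fewer heterotrophic taxa than n_culturable")
  }
  cult <- sample(het, config$n_culturable,
                 prob = base[het]^0.5)  # mild bias toward abundant taxa
  culturable <- ids[sort(cult)]

  strata <- .strata_of(config)
  abundance <- matrix(0, nrow = nrow(strata), ncol = n,
                      dimnames = list(strata$stratum, ids))
  in_c <- ids %in% culturable
  for (s in seq_len(nrow(strata))) {
    noise <- stats::rlnorm(n, 0, 0.3)   # per-stratum compositional jitter
    a <- base * noise
    f <- strata$f_planted[s]
    a[in_c] <- f * a[in_c] / sum(a[in_c])
    a[!in_c] <- (1 - f) * a[!in_c] / sum(a[!in_c])
    abundance[s, ] <- a
  }

  cn <- rep(1, n)
  if (config$copy_number_model == "inflated") {
    cn[in_c] <- stats::rlnorm(sum(in_c), log(config$copy_median),
                              config$copy_sdlog)
    cn[in_c] <- pmax(1, cn[in_c])
  }
  copy_numbers <- data.frame(genus = genus, copy_number = cn,
                             stringsAsFactors = FALSE)

  list(asv_seqs = seqs, taxonomy = taxonomy, copy_numbers = copy_numbers,
       abundance = abundance, strata = strata, culturable = culturable,
       truth = list(culturable = culturable,
                    f_planted = stats::setNames(strata$f_planted,
                                                strata$stratum),
                    roles = stats::setNames(roles, ids)))
}

#' Simulate read counts and sample metadata
#'
#' Per-sample multinomial draws with probabilities proportional to
#' cell abundance times rRNA operon copy number; sample totals equal
#' \code{reads_per_sample} up to the configured jitter. Stations are
#' assigned within layers from a shared station pool.
#'
#' @param community A \code{\link{simulate_community}} result.
#' @param config The same \code{\link{sim_config}}.
#' @return List: counts (samples x ASVs integer matrix), meta (data.frame
#'   sample_id, dataset, layer, size_fraction, station_id).
#' @export
simulate_counts <- function(community, config) {
  set.seed(config$seed + 1L)
  strata <- community$strata
  cn <- community$copy_numbers$copy_number
  n_per <- config$n_samples_per_stratum
  n_samples <- nrow(strata) * n_per
  counts <- matrix(0L, nrow = n_samples, ncol = config$n_taxa,
                   dimnames = list(sprintf("S%03d", seq_len(n_samples)),
                                   colnames(community$abundance)))
  meta <- vector("list", nrow(strata))
  # station pool split across layers
  st_ids <- sprintf("st%02d", seq_len(config$n_stations))
  layer_pool <- split(st_ids, rep_len(config$layers, config$n_stations))
  row <- 0L
  for (s in seq_len(nrow(strata))) {
    prob <- community$abundance[s, ] * cn
    pool <- layer_pool[[strata$layer[s]]]
    stations <- pool[1L + (seq_len(n_per) - 1L) %% length(pool)]
    for (j in seq_len(n_per)) {
      row <- row + 1L
      depth <- round(config$reads_per_sample *
                       stats::runif(1L, 1 - config$reads_jitter,
                                    1 + config$reads_jitter))
      counts[row, ] <- as.integer(stats::rmultinom(1L, depth, prob))
    }
    meta[[s]] <- data.frame(
      sample_id = rownames(counts)[(row - n_per + 1L):row],
      dataset = "synthetic",
      layer = strata$layer[s],
      size_fraction = strata$size_fraction[s],
      station_id = stations,
      stringsAsFactors = FALSE)
  }
  list(counts = counts, meta = do.call(rbind, meta))
}

#' Simulate the culture collection
#'
#' Isolates are drawn from the culturable taxa with probability
#' proportional to mean abundance^beta (the copiotroph bias); with
#' \code{ensure_coverage} every culturable taxon contributes at least one
#' isolate first. Each isolate sequence embeds its source ASV region
#' verbatim between concrete realizations of the primer sites, flanked by
#' random sequence, so region extraction is exercised end to end. A
#' \code{nonmatch_fraction} of isolates receive one substitution inside the
#' region and can no longer match any ASV.
#'
#' @param community A \code{\link{simulate_community}} result.
#' @param config The same \code{\link{sim_config}}.
#' @return List: sequences (named by isolate id), meta (isolate metadata
#'   data.frame), truth (source_taxon map, planted_nonmatch ids).
#' @export
simulate_isolates <- function(community, config) {
  set.seed(config$seed + 2L)
  cult <- community$culturable
  if (!length(cult)) stop("no culturable taxa to isolate from")
  mean_ab <- colMeans(community$abundance)[cult]
  w <- mean_ab^config$copiotroph_bias
  n_iso <- config$isolate_count
  src <- character(0L)
  if (config$ensure_coverage) {
    src <- cult
  }
  n_extra <- n_iso - length(src)
  if (n_extra < 0L) {
    src <- sample(cult, n_iso, prob = w)
    n_extra <- 0L
  }
  if (n_extra > 0L) {
    src <- c(src, sample(cult, n_extra, replace = TRUE, prob = w))
  }
  src <- sample(src)   # shuffle isolate order
  iso_ids <- sprintf("ISO_%04d", seq_along(src))

  fwd_site <- .concretize_primer(PRIMER_515FY)
  rev_site <- reverse_complement(.concretize_primer(PRIMER_926R))
  regions <- community$asv_seqs[src]

  nonmatch <- sample(seq_along(src), round(config$nonmatch_fraction *
                                             length(src)))
  for (i in nonmatch) {
    r <- regions[[i]]
    pos <- sample.int(nchar(r), 1L)
    old <- substr(r, pos, pos)
    substr(r, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    regions[i] <- r
  }
  flank5 <- .random_dna(length(src), 40L)
  flank3 <- .random_dna(length(src), 40L)
  seqs <- paste0(flank5, fwd_site, regions, rev_site, flank3)
  names(seqs) <- iso_ids

  # isolate metadata: layers weighted toward where the culturable subset
  # is abundant; stations from the per-layer pools
  layer_w <- config$culturable_read_fraction[config$layers]
  st_ids <- sprintf("st%02d", seq_len(config$n_stations))
  layer_pool <- split(st_ids, rep_len(config$layers, config$n_stations))
  sample_layer <- sample(config$layers, length(src), replace = TRUE,
                         prob = layer_w)
  iso_layer <- ifelse(sample_layer %in% c("SRF", "DCM"), "PHOTIC", sample_layer)
  station <- vapply(sample_layer, function(l) sample(layer_pool[[l]], 1L),
                    character(1L))
  genus <- vapply(strsplit(community$taxonomy[src], ";", fixed = TRUE),
                  `[`, character(1L), 6L)
  meta <- data.frame(isolate_id = iso_ids, station_id = unname(station),
                     layer = iso_layer, genus = unname(genus),
                     medium = "MarineAgar", stringsAsFactors = FALSE)
  list(sequences = seqs, meta = meta,
       truth = list(source_taxon = stats::setNames(src, iso_ids),
                    planted_nonmatch = iso_ids[sort(nonmatch)]))
}

#' Simulate per-station colony and cell counts
#'
#' Cells per ml drawn lognormal per layer (decreasing with depth);
#' cultivability drawn per layer from Beta distributions whose means
#' reproduce the field pattern (photic ~0.3\%, mesopelagic and bathypelagic
#' ~1.3\%, the deep layers more variable). The drawn cultivability is
#' recorded as truth.
#'
#' @param config A \code{\link{sim_config}}.
#' @return data.frame station_id, layer, cfu_per_ml, cells_per_ml with
#'   attribute \code{truth} (drawn cultivability fractions).
#' @export
simulate_station_counts <- function(config) {
  set.seed(config$seed + 3L)
  n_layer <- c(PHOTIC = 12L, MESO = 4L, BATHY = 7L)
  cells_meanlog <- c(PHOTIC = log(6e5), MESO = log(1.2e5), BATHY = log(4e4))
  beta_shapes <- list(PHOTIC = c(1.2, 400), MESO = c(4, 300),
                      BATHY = c(2, 150))
  rows <- lapply(names(n_layer), function(l) {
    k <- n_layer[[l]]
    cells <- stats::rlnorm(k, cells_meanlog[[l]], 0.5)
    p <- stats::rbeta(k, beta_shapes[[l]][1L], beta_shapes[[l]][2L])
    data.frame(station_id = sprintf("%s_st%02d", tolower(l), seq_len(k)),
               layer = l, cfu_per_ml = cells * p, cells_per_ml = cells,
               cultivability = p, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  truth <- stats::setNames(df$cultivability, df$station_id)
  df$cultivability <- NULL
  attr(df, "truth") <- truth
  df
}

#' Simulate a complete synthetic study
#'
#' Runs \code{\link{simulate_community}}, \code{\link{simulate_counts}},
#' \code{\link{simulate_isolates}} and
#' \code{\link{simulate_station_counts}} under one configuration and
#' returns every input the analysis pipeline consumes plus the combined
#' ground truth. Deterministic per (config, seed).
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{synthetic_study}: asv_seqs, taxonomy, counts,
#'   sample_meta, isolate_seqs, isolate_meta, copy_numbers,
#'   station_counts, truth, config.
#' @export
simulate_study <- function(config) {
  comm <- simulate_community(config)
  cnt <- simulate_counts(comm, config)
  iso <- simulate_isolates(comm, config)
  st <- simulate_station_counts(config)
  truth <- c(comm$truth, iso$truth,
             list(station_cultivability = attr(st, "truth"),
                  abundance = comm$abundance,
                  copy_numbers = comm$copy_numbers))
  structure(list(asv_seqs = comm$asv_seqs, taxonomy = comm$taxonomy,
                 counts = cnt$counts, sample_meta = cnt$meta,
                 isolate_seqs = iso$sequences, isolate_meta = iso$meta,
                 copy_numbers = comm$copy_numbers, station_counts = st,
                 truth = truth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "synthetic_study: %d ASVs, %d samples (%d strata), %d isolates, seed %d\n",
    length(x$asv_seqs), nrow(x$counts), nrow(unique(
      x$sample_meta[, c("layer", "size_fraction")])),
    length(x$isolate_seqs), x$config$seed))
  cat("  planted culturable read fractions:\n")
  f <- x$truth$f_planted
  for (s in names(f)) cat(sprintf("    %-14s %.3f\n", s, f[[s]]))
  invisible(x)
}
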