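# Synthetic-data generators: reference transcripts, diploid pool genotypes,
# pooled reads with per-base qualities, and biallelic genotype panels.
# Every generator takes an explicit seed and is bit-reproducible.

#' Population model for two pooled samples
#'
#' Describes two populations sampled as small pools of diploid individuals.
#' Per-site population allele frequencies are drawn per `freq_spec`, which
#' supports the three cross-pool regimes seen in pooled resequencing:
#' polymorphic in both populations, fixed in one and polymorphic in the
#' other, and fixed for different alleles.
#'
#' @param n_individuals_per_pool diploid individuals per pool (default 3)
#' @param variable_site_density expected variable sites per reference base
#' @param prop_fixed_different fraction of variable sites fixed for
#'   alternate alleles in the two populations (alt frequencies 1/0 or 0/1)
#' @param freq_fun function(n) returning n population alt-allele frequencies
#'   in \[0,1\] for one pool; applied independently to each pool at the
#'   non-fixed-different sites. Default: uniform on (0,1).
#' @param seed integer seed
#' @return a `population_model` list
#' @export
population_model <- function(n_individuals_per_pool = 3L,
                             variable_site_density = 0.005,
                             prop_fixed_different = 0.02,
                             freq_fun = stats::runif,
                             seed = 1L) {
  if (n_individuals_per_pool < 1) stopf("need at least one individual per pool")
  if (variable_site_density <= 0) stopf("variable_site_density must be > 0")
  if (prop_fixed_different < 0 || prop_fixed_different > 1)
    stopf("prop_fixed_different must be in [0,1]")
  structure(list(n_individuals_per_pool = as.integer(n_individuals_per_pool),
                 variable_site_density = variable_site_density,
                 prop_fixed_different = prop_fixed_different,
                 freq_fun = freq_fun,
                 seed = as.integer(seed)),
            class = "population_model")
}

#' Sequencing model for pooled single-end reads
#'
#' @param mean_depth_per_pool target reads-per-base depth in each pool
#' @param read_length_mean mean read length in bases; a single value or a
#'   named vector c(high=, low=) for pool-specific lengths
#' @param read_length_sd standard deviation of read length
#' @param substitution_error_rate per-base substitution probability
#' @param q_correct phred quality assigned to correctly sequenced bases
#' @param q_error_range inclusive phred range for erroneous bases (uniform)
#' @param seed integer seed
#' @return a `sequencing_model` list
#' @export
sequencing_model <- function(mean_depth_per_pool = 30,
                             read_length_mean = c(high = 266.8, low = 245.7),
                             read_length_sd = 60,
                             substitution_error_rate = 0.005,
                             q_correct = 30L,
                             q_error_range = c(10L, 30L),
                             seed = 1L) {
  if (mean_depth_per_pool <= 0) stopf("mean_depth_per_pool must be > 0")
  if (substitution_error_rate < 0 || substitution_error_rate >= 1)
    stopf("substitution_error_rate must be in [0,1)")
  if (q_correct < 0 || q_correct > 41 || any(q_error_range < 0) || any(q_error_range > 41))
    stopf("phred qualities must be representable in 0-41")
  structure(list(mean_depth_per_pool = mean_depth_per_pool,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 substitution_error_rate = substitution_error_rate,
                 q_correct = as.integer(q_correct),
                 q_error_range = as.integer(q_error_range),
                 seed = as.integer(seed)),
            class = "sequencing_model")
}

#' Generate random reference transcript sequences
#'
#' @param n_transcripts number of transcripts (>= 1)
#' @param length_mean mean transcript length in bases
#' @param length_sd standard deviation of lengths; 0 gives every transcript
#'   exactly `length_mean` bases
#' @param min_length lower truncation for sampled lengths
#' @param seed integer seed
#' @return named DNAStringSet of transcripts (ids tig000001, ...)
#' @export
generate_reference <- function(n_transcripts, length_mean = 1000,
                               length_sd = 250, min_length = 200L,
                               seed = 1L) {
  if (n_transcripts < 1) stopf("n_transcripts must be >= 1")
  if (length_mean < 1) stopf("length_mean must be >= 1")
  if (length_sd < 0) stopf("length_sd must be >= 0")
  set.seed(derive_seed(seed, 101L))
  lens <- pmax(as.integer(min_length),
               as.integer(round(stats::rnorm(n_transcripts, length_mean, length_sd))))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(lens, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("tig%06d", seq_len(n_transcripts))
  x
}

#' Simulate diploid genotypes for two pooled populations
#'
#' Places variable sites along the reference at the model's density, draws a
#' pair of population alt-allele frequencies (f_high, f_low) per site, then
#' draws each individual's genotype as Binomial(2, f). Alt alleles are phased
#' onto haplotypes so reads can be simulated from concrete chromosomes. The
#' returned truth table is the ground truth for parameter-recovery tests.
#'
#' @param model a `population_model`
#' @param reference named DNAStringSet (or named character vector)
#' @return a `truth_table` list with elements:
#'   \describe{
#'     \item{sites}{data.table: contig, pos (1-based), ref, alt, f_high,
#'       f_low, alt_count_high, alt_count_low (alt chromosomes out of 2n),
#'       pool_freq_high, pool_freq_low, and per-individual dosages}
#'     \item{haplotypes}{data.table: pool, individual, hap, contig, seq}
#'     \item{n_individuals_per_pool}{n per pool}
#'   }
#' @export
simulate_pool_genotypes <- function(model, reference) {
  stopifnot(inherits(model, "population_model"))
  ref <- ref_as_character(reference)
  if (length(ref) == 0) stopf("reference is empty")
  set.seed(derive_seed(model$seed, 211L))
  n <- model$n_individuals_per_pool
  lens <- nchar(ref)

  # variable-site placement: Binomial(len, density) sites per contig
  n_sites <- stats::rbinom(length(ref), lens, model$variable_site_density)
  pos_list <- lapply(seq_along(ref), function(i) sort(sample.int(lens[i], n_sites[i])))
  sites <- data.table(contig = rep(names(ref), n_sites), pos = unlist(pos_list))
  if (nrow(sites) == 0) stopf("no variable sites drawn; increase density or reference size")
  sites[, ref_base := substring(ref[contig], pos, pos)]
  bases <- c("A", "C", "G", "T")
  sites[, alt := vapply(ref_base, function(b) sample(setdiff(bases, b), 1L), character(1))]
  setnames(sites, "ref_base", "ref")

  m <- nrow(sites)
  fixed_diff <- stats::runif(m) < model$prop_fixed_different
  f_high <- model$freq_fun(m)
  f_low <- model$freq_fun(m)
  if (any(f_high < 0 | f_high > 1 | f_low < 0 | f_low > 1))
    stopf("freq_fun produced frequencies outside [0,1]")
  orient <- stats::runif(sum(fixed_diff)) < 0.5
  f_high[fixed_diff] <- ifelse(orient, 1, 0)
  f_low[fixed_diff] <- ifelse(orient, 0, 1)
  sites[, `:=`(f_high = f_high, f_low = f_low, fixed_different = fixed_diff)]

  # per-individual alt dosages, phased onto two haplotypes
  hap_alt <- list()  # [[pool]][[ind]][[hap]] = logical vector over sites
  for (pool in c("high", "low")) {
    f <- if (pool == "high") sites$f_high else sites$f_low
    for (ind in seq_len(n)) {
      a1 <- stats::runif(m) < f
      a2 <- stats::runif(m) < f
      hap_alt[[pool]][[ind]] <- list(a1, a2)
      sites[, (sprintf("gt_%s_%d", pool, ind)) := as.integer(a1) + as.integer(a2)]
    }
    dosage_cols <- sprintf("gt_%s_%d", pool, seq_len(n))
    sites[, (sprintf("alt_count_%s", pool)) := rowSums(.SD), .SDcols = dosage_cols]
    sites[, (sprintf("pool_freq_%s", pool)) :=
              get(sprintf("alt_count_%s", pool)) / (2 * n)]
  }

  # concrete haplotype sequences per pool/individual/chromosome
  hap_rows <- list()
  for (pool in c("high", "low")) for (ind in seq_len(n)) for (h in 1:2) {
    carries <- hap_alt[[pool]][[ind]][[h]]
    seqs <- ref
    if (any(carries)) {
      sub <- sites[carries, .(contig, pos, alt)]
      for (tg in unique(sub$contig)) {
        s <- seqs[[tg]]
        rows <- sub[contig == tg]
        for (j in seq_len(nrow(rows)))
          substr(s, rows$pos[j], rows$pos[j]) <- rows$alt[j]
        seqs[[tg]] <- s
      }
    }
    hap_rows[[length(hap_rows) + 1L]] <-
      data.table(pool = pool, individual = ind, hap = h,
                 contig = names(seqs), seq = unname(seqs))
  }

  structure(list(sites = sites[], haplotypes = rbindlist(hap_rows),
                 n_individuals_per_pool = n,
                 reference = ref),
            class = "truth_table")
}

#' Write a truth table's site records as TSV (1-based positions)
#' @param truth a `truth_table`
#' @param path output TSV path
#' @export
write_truth_table <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  fwrite(truth$sites, path, sep = "\t")
  invisible(path)
}

#' Simulate pooled single-end reads for both pools
#'
#' Reads are drawn uniformly across individuals and haplotypes within each
#' pool, with uniform start positions and lengths clipped at transcript
#' ends. Substitution errors are introduced at the model's rate; correct
#' bases get `q_correct`, erroneous bases a uniform draw from
#' `q_error_range`. Read names are "pool:contig:start:indN.hapH:serial" so
#' each read's origin can be checked against the truth table.
#'
#' @param truth a `truth_table` from [simulate_pool_genotypes()]
#' @param seqmodel a `sequencing_model`
#' @return named list of two `read_set`s: `high` and `low`
#' @export
simulate_pooled_reads <- function(truth, seqmodel) {
  stopifnot(inherits(truth, "truth_table"), inherits(seqmodel, "sequencing_model"))
  if (nrow(truth$sites) == 0) stopf("truth table has no sites")
  ref_len <- nchar(truth$reference)
  if (sum(ref_len) == 0) stopf("zero-length reference")
  out <- list()
  for (pool in c("high", "low")) {
    set.seed(derive_seed(seqmodel$seed, if (pool == "high") 311L else 312L))
    lm <- seqmodel$read_length_mean
    mean_len <- if (length(lm) > 1) unname(lm[[pool]]) else unname(lm)
    total <- seqmodel$mean_depth_per_pool * sum(ref_len)
    n_reads <- max(1L, as.integer(round(total / mean_len)))

    want_pool <- truth$haplotypes$pool == pool
    haps <- truth$haplotypes[want_pool]
    n_ind <- truth$n_individuals_per_pool
    contigs <- names(truth$reference)
    tg_idx <- sample.int(length(contigs), n_reads, replace = TRUE,
                         prob = ref_len / sum(ref_len))
    rd_ind <- sample.int(n_ind, n_reads, replace = TRUE)
    rd_hap <- sample.int(2L, n_reads, replace = TRUE)
    lens <- pmax(30L, as.integer(round(stats::rnorm(n_reads, mean_len,
                                                    seqmodel$read_length_sd))))
    clen <- ref_len[tg_idx]
    lens <- pmin(lens, clen)
    start <- 1L + as.integer(floor(stats::runif(n_reads) * (clen - lens + 1)))

    setkey(haps, individual, hap, contig)
    hseq <- haps[.(rd_ind, rd_hap, contigs[tg_idx]), seq]
    seqs <- substr(hseq, start, start + lens - 1L)

    # substitution errors + qualities
    n_err <- stats::rbinom(n_reads, lens, seqmodel$substitution_error_rate)
    quals <- vector("list", n_reads)
    qc <- seqmodel$q_correct
    qr <- seqmodel$q_error_range
    bases <- c("A", "C", "G", "T")
    err_reads <- which(n_err > 0)
    for (i in err_reads) {
      p <- sample.int(lens[i], n_err[i])
      s <- seqs[i]
      for (j in p) {
        old <- substr(s, j, j)
        substr(s, j, j) <- sample(setdiff(bases, old), 1L)
      }
      seqs[i] <- s
      q <- rep.int(qc, lens[i])
      q[p] <- sample(qr[1]:qr[2], n_err[i], replace = TRUE)
      quals[[i]] <- q
    }
    qual_str <- character(n_reads)
    plain <- phred_to_string(rep.int(qc, max(lens)))
    qual_str[] <- substr(rep(plain, n_reads), 1L, lens)
    for (i in err_reads) qual_str[i] <- phred_to_string(quals[[i]])

    ids <- sprintf("%s:%s:%d:ind%d.hap%d:%07d",
                   pool, contigs[tg_idx], start, rd_ind, rd_hap, seq_len(n_reads))
    out[[pool]] <- read_set(ids, seqs, qual_str, pool = pool)
  }
  out
}

#' Simulate a biallelic genotype sample under an inbreeding model
#'
#' Genotype probabilities are (p^2 + f p q, 2 p q (1 - f), q^2 + f p q),
#' the standard inbreeding decomposition; f = 0 is Hardy-Weinberg
#' equilibrium, f = 1 gives no heterozygotes.
#'
#' @param p alt ("A") allele frequency in \[0,1\]
#' @param n number of diploid individuals
#' @param inbreeding_f inbreeding coefficient in \[0,1\]
#' @param seed integer seed
#' @return character vector of genotypes in c("AA","Aa","aa")
#' @export
simulate_genotype_panel <- function(p, n, inbreeding_f = 0, seed = 1L) {
  if (p < 0 || p > 1) stopf("p must be in [0,1]")
  if (n < 1) stopf("n must be >= 1")
  if (inbreeding_f < 0 || inbreeding_f > 1) stopf("inbreeding_f must be in [0,1]")
  q <- 1 - p
  probs <- c(AA = p^2 + inbreeding_f * p * q,
             Aa = 2 * p * q * (1 - inbreeding_f),
             aa = q^2 + inbreeding_f * p * q)
  if (any(probs < -1e-12) || abs(sum(probs) - 1) > 1e-9)
    stopf("invalid genotype probabilities")
  probs <- pmax(probs, 0)
  set.seed(derive_seed(seed, 401L))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate a multi-locus validation panel across site/elevation groups
#'
#' Convenience builder for a genotype panel shaped like a validation study:
#' `n_loci` biallelic loci typed in four groups (two sites x two
#' elevations), each group with its own sample size and per-locus allele
#' frequencies drawn uniformly.
#'
#' @param n_loci number of loci
#' @param group_sizes named integer vector of individuals per group
#' @param inbreeding_f inbreeding coefficient shared by all groups
#' @param seed integer seed
#' @return data.table: locus, group, site, elevation, individual, genotype
#' @export
simulate_validation_panel <- function(n_loci = 17L,
                                      group_sizes = c(BC_high = 10L, BC_low = 11L,
                                                      OR_high = 10L, OR_low = 11L),
                                      inbreeding_f = 0, seed = 1L) {
  set.seed(derive_seed(seed, 402L))
  rows <- list()
  for (l in seq_len(n_loci)) {
    for (g in names(group_sizes)) {
      p <- stats::runif(1)
      gt <- simulate_genotype_panel(p, group_sizes[[g]], inbreeding_f,
                                    seed = derive_seed(seed, 500L + l) + match(g, names(group_sizes)))
      parts <- strsplit(g, "_", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.table(
        locus = sprintf("Locus%03d", l), group = g,
        site = parts[1], elevation = parts[2],
        individual = sprintf("%s_%02d", g, seq_along(gt)), genotype = gt)
    }
  }
  rbindlist(rows)
}

#' Write/read model configuration as JSON
#'
#' The resolved population and sequencing models are serialized so a run's
#' conditions travel with its outputs.
#' @param popmodel a `population_model`
#' @param seqmodel a `sequencing_model`
#' @param path output JSON path
#' @export
write_model_config <- function(popmodel, seqmodel, path) {
  pm <- unclass(popmodel)
  pm$freq_fun <- paste(deparse(pm$freq_fun), collapse = " ")
  jsonlite::write_json(list(population_model = pm,
                            sequencing_model = unclass(seqmodel)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
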