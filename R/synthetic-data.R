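#' Synthetic amplicon metabarcoding data with known ground truth
#'
#' The generators in this file emulate every input of the diet-metabarcoding
#' pipeline: an ITS2-like plant reference database, paired-end amplicon reads
#' with sequencing error and 3'-decaying qualities, mock communities in known
#' ratios, bait (millet) contamination, sample metadata, and plant
#' cover/phenology surveys whose seed availability is linked to diet through
#' planted selection coefficients. All generators are byte-reproducible under
#' a fixed seed.
#'
#' @name synthetic_data
NULL

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Fixed synthetic primer pair
#'
#' Two fixed 20-mers standing in for the forward and reverse ITS2 primers.
#' The simulated amplicon is `forward + insert + revcomp(reverse)`, so the
#' first mate begins with the forward primer and the second mate begins with
#' the reverse primer, as on a real sequencer.
#'
#' @return named list with `fwd` and `rev` primer strings.
#' @export
primer_set <- function() {
  list(fwd = "ATGCGTACGTTGACCTGAAT",
       rev = "TCCGATGGACTTGAACGCAT")
}

#' Generate a synthetic plant reference database
#'
#' Each genus descends from an independent random ancestor; congeneric
#' species are derived by substituting bases at rate `divergence`, so
#' within-genus identity exceeds between-genus identity by construction.
#'
#' @param n_genera number of genera (>= 2).
#' @param species_per_genus species per genus.
#' @param length_range integer pair within \[200, 450\]; amplicon insert
#'   lengths are drawn uniformly from this range per genus.
#' @param divergence per-base substitution rate between congeners.
#' @param seed RNG seed.
#' @param genus_names optional genus labels (e.g. to include the bait genus
#'   `"Panicum"`); defaults to `Genus01`, `Genus02`, ...
#' @return data.frame with columns accession, genus, species, growth_form,
#'   native, sequence.
#' @export
generate_reference <- function(n_genera, species_per_genus = 1L,
                               length_range = c(250L, 420L),
                               divergence = 0.02, seed = 1L,
                               genus_names = NULL) {
  if (n_genera < 2) stopf("n_genera must be >= 2, got %d", n_genera)
  if (species_per_genus < 1) stopf("species_per_genus must be >= 1")
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 200 || length_range[2] > 450)
    stopf("length_range must be an increasing pair within [200, 450]")
  if (is.null(genus_names))
    genus_names <- sprintf("Genus%02d", seq_len(n_genera))
  if (length(genus_names) != n_genera) stopf("need %d genus names", n_genera)

  with_seed(seed, {
    growth_forms <- c("forb", "grass", "shrub", "tree")
    rows <- vector("list", n_genera * species_per_genus)
    idx <- 0L
    for (g in seq_len(n_genera)) {
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      ancestor <- random_dna(len)
      gform <- sample(growth_forms, 1L, prob = c(0.5, 0.2, 0.2, 0.1))
      native <- runif(1) < 0.7
      for (s in seq_len(species_per_genus)) {
        idx <- idx + 1L
        nmut <- rbinom(1L, len, divergence)
        pos <- if (nmut > 0) sample(len, nmut) else integer(0)
        rows[[idx]] <- data.frame(
          accession = sprintf("ACC%04d", idx),
          genus = genus_names[g],
          species = sprintf("%s sp%02d", genus_names[g], s),
          growth_form = gform,
          native = native,
          sequence = mutate_bases(ancestor, pos),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# per-read substitution errors at `rate`; returns mutated sequences
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- rbinom(length(seqs), lens, rate)
  hit <- which(nerr > 0L)
  for (i in hit) {
    seqs[i] <- mutate_bases(seqs[i], sample(lens[i], nerr[i]))
  }
  seqs
}

# per-read indels (insertion or deletion of 1 base) at `rate`
apply_indels <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nind <- rbinom(length(seqs), lens, rate)
  hit <- which(nind > 0L)
  for (i in hit) {
    s <- seqs[i]
    for (k in seq_len(nind[i])) {
      L <- nchar(s)
      p <- sample(L, 1L)
      if (runif(1) < 0.5) {
        s <- paste0(substr(s, 1, p), sample(DNA_BASES, 1L), substr(s, p + 1, L))
      } else if (L > 1) {
        s <- paste0(substr(s, 1, p - 1L), substr(s, p + 1, L))
      }
    }
    seqs[i] <- s
  }
  seqs
}

# Phred+33 quality strings with a linearly decaying mean and Gaussian jitter
simulate_qualities <- function(lens, q_start = 38, decay = 18, jitter_sd = 3,
                               read_len = max(lens)) {
  vapply(lens, function(L) {
    mu <- q_start - decay * (seq_len(L) - 1) / max(read_len - 1, 1)
    q <- round(mu + rnorm(L, 0, jitter_sd))
    int_to_phred(pmin(pmax(q, 2L), 41L))
  }, character(1))
}

#' Simulate paired-end amplicon reads for one fecal sample
#'
#' Reads are drawn multinomially across genera according to `profile`
#' (optionally mixed with a bait genus), each covering a reference amplicon
#' from both ends with the synthetic primers prepended. Substitution and
#' indel errors are applied per mate; qualities decay toward the 3' end.
#'
#' @param profile named per-genus proportions summing to 1 (tolerance 1e-6).
#' @param ref reference database from [generate_reference()].
#' @param n_pairs number of read pairs.
#' @param error_rate per-base substitution rate in \[0, 0.2\].
#' @param indel_rate per-base indel rate in \[0, 0.2\].
#' @param quality_decay total mean Phred drop across the read.
#' @param read_len mate length (reads are capped at the amplicon length).
#' @param bait optional `list(genus =, level =)`: the profile is rescaled to
#'   `(1 - level) * profile` plus `level` on the bait genus.
#' @param seed RNG seed.
#' @param sample_id prefix for read ids.
#' @return list with `pairs` (data.frame id, seq1, qual1, seq2, qual2),
#'   `truth` (realized per-genus proportions) and `truth_counts`.
#' @export
generate_sample_reads <- function(profile, ref, n_pairs,
                                  error_rate = 0.002, indel_rate = 0,
                                  quality_decay = 18, read_len = 300L,
                                  bait = NULL, seed = 1L,
                                  sample_id = "S1") {
  if (abs(sum(profile) - 1) > 1e-6)
    stopf("profile must sum to 1 (got %.8f)", sum(profile))
  if (error_rate < 0 || error_rate > 0.2 || indel_rate < 0 || indel_rate > 0.2)
    stopf("error rates must lie in [0, 0.2]")
  if (!is.null(bait)) {
    profile <- profile * (1 - bait$level)
    profile[bait$genus] <- sum(profile[bait$genus], bait$level, na.rm = TRUE)
  }
  missing <- setdiff(names(profile)[profile > 0], ref$genus)
  if (length(missing) > 0)
    stopf("profile taxa not in reference: %s", paste(missing, collapse = ", "))

  primers <- primer_set()
  with_seed(seed, {
    genera <- names(profile)
    counts <- as.vector(rmultinom(1L, n_pairs, profile))
    names(counts) <- genera

    ids <- sprintf("%s_read%06d", sample_id, seq_len(n_pairs))
    seq1 <- seq2 <- character(n_pairs)
    offset <- 0L
    genus_of_read <- character(n_pairs)
    for (g in genera) {
      ng <- counts[[g]]
      if (ng == 0L) next
      members <- which(ref$genus == g)
      pick <- members[sample.int(length(members), ng, replace = TRUE)]
      amplicon <- paste0(primers$fwd, ref$sequence[pick], revcomp(primers$rev))
      take <- pmin(read_len, nchar(amplicon))
      i <- offset + seq_len(ng)
      seq1[i] <- substr(amplicon, 1L, take)
      rc <- revcomp(amplicon)
      seq2[i] <- substr(rc, 1L, take)
      genus_of_read[i] <- g
      offset <- offset + ng
    }
    seq1 <- apply_indels(apply_substitutions(seq1, error_rate), indel_rate)
    seq2 <- apply_indels(apply_substitutions(seq2, error_rate), indel_rate)
    qual1 <- simulate_qualities(nchar(seq1), decay = quality_decay,
                                read_len = read_len)
    qual2 <- simulate_qualities(nchar(seq2), decay = quality_decay,
                                read_len = read_len)
    pairs <- data.frame(id = ids, seq1 = seq1, qual1 = qual1,
                        seq2 = seq2, qual2 = qual2, stringsAsFactors = FALSE)
    list(pairs = pairs,
         truth = counts / n_pairs,
         truth_counts = counts,
         genus_of_read = stats::setNames(genus_of_read, ids))
  })
}

#' Simulate a mock community read pair set
#'
#' A control sample in known taxon ratios and no bait, used to validate
#' quantification end to end.
#'
#' @param truth named per-genus proportions summing to 1.
#' @inheritParams generate_sample_reads
#' @return as [generate_sample_reads()].
#' @export
generate_mock_pair <- function(truth, ref, n_pairs, seed = 1L,
                               error_rate = 0.002, read_len = 300L,
                               sample_id = "mock") {
  generate_sample_reads(truth, ref, n_pairs, error_rate = error_rate,
                        read_len = read_len, bait = NULL, seed = seed,
                        sample_id = sample_id)
}

#' Map calendar dates to rodent activity seasons
#'
#' Spring = March-June, summer = July-August, fall = September-October;
#' winter months are outside the above-ground activity period and rejected.
#'
#' @param dates Date vector (or strings coercible to Date).
#' @return character vector in {"spring", "summer", "fall"}.
#' @export
season_of_date <- function(dates) {
  dates <- as.Date(dates)
  m <- as.integer(format(dates, "%m"))
  out <- rep(NA_character_, length(m))
  out[m >= 3 & m <= 6] <- "spring"
  out[m %in% c(7L, 8L)] <- "summer"
  out[m %in% c(9L, 10L)] <- "fall"
  if (anyNA(out))
    stopf("dates outside the defined activity seasons: %s",
          paste(format(dates[is.na(out)]), collapse = ", "))
  out
}

# Dirichlet draw
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x <- rep(1, length(alpha))
  x / sum(x)
}

# Split a base composition b into availability a and diet d, both summing
# to 1, with d_i / a_i = w_i exactly: a ~ b * w^-t, d ~ b * w^(1-t) share a
# normalizer when t solves sum(b w^-t (w - 1)) = 0 (monotone in t; a root
# exists when the coefficients are mixed-sign). With one-sided coefficients
# no such pair exists (both must sum to 1), so the diet is then the plain
# exponential tilt of the availability.
link_diet_availability <- function(b, w) {
  if (all(w == 1)) return(list(availability = b, diet = b))
  g <- function(t) sum(b * w^(-t) * (w - 1))
  root <- tryCatch(
    stats::uniroot(g, c(-20, 20), extendInt = "downX", tol = 1e-12)$root,
    error = function(e) NA_real_)
  if (is.na(root)) {
    a <- b
    d <- b * w
    return(list(availability = a, diet = d / sum(d)))
  }
  a <- b * w^(-root)
  list(availability = a / sum(a), diet = (a * w) / sum(a * w))
}

#' Generate linked phenology surveys, availability and diet truth
#'
#' For each (grid, session) a habitat availability composition is drawn from
#' a Dirichlet; the matching diet composition is the availability tilted by
#' the planted per-genus selection coefficients,
#' `diet ~ availability * exp(coef)` renormalized. The phenology survey is
#' constructed so that cover-weighted seed-state sums recover availability:
#' per-plot percent cover is proportional to availability (with plot-level
#' noise) and the flowering/set seed/seeded fractions are held constant.
#'
#' @param ref reference database (genera define the taxon universe).
#' @param grids data.frame(grid, site) or character vector of grid labels.
#' @param sessions Date vector of survey sessions (spring/summer/fall only).
#' @param selection named per-genus selection coefficients (log fold
#'   preference; 0 = neutral). Missing genera default to 0.
#' @param concentration Dirichlet concentration for availability draws.
#' @param samples_per_gs fecal samples per (grid, session).
#' @param n_plots survey plots per grid.
#' @param cover_noise_sd lognormal sd of per-plot cover noise.
#' @param seed RNG seed.
#' @return list with `survey` (plot-level phenology rows), `metadata`
#'   (per fecal sample site/grid/year/season/session), `availability_truth`
#'   and `diet_truth` ((grid|session) x genus matrices), and `selection`.
#' @export
generate_phenology <- function(ref, grids, sessions, selection = NULL,
                               concentration = 5, samples_per_gs = 5L,
                               n_plots = 8L, cover_noise_sd = 0.15,
                               seed = 1L) {
  if (is.character(grids))
    grids <- data.frame(grid = grids, site = "SITE1", stringsAsFactors = FALSE)
  sessions <- sort(as.Date(sessions))
  seasons <- season_of_date(sessions)     # errors on out-of-season dates
  genera <- unique(ref$genus)
  coef <- stats::setNames(rep(0, length(genera)), genera)
  if (!is.null(selection)) coef[names(selection)] <- selection

  state_frac <- c(new_growth = 0.1, budding = 0.1, flowering = 0.3,
                  set_seed = 0.18, seeded = 0.12, dead = 0)

  with_seed(seed, {
    survey <- list(); meta <- list()
    keys <- character(0)
    avail <- diet <- NULL
    for (gi in seq_len(nrow(grids))) {
      for (si in seq_along(sessions)) {
        b <- rdirichlet1(rep(concentration, length(genera)))
        linked <- link_diet_availability(b, exp(coef))
        a <- stats::setNames(linked$availability, genera)
        d <- stats::setNames(linked$diet, genera)
        key <- paste(grids$grid[gi], format(sessions[si]), sep = "|")
        keys <- c(keys, key)
        avail <- rbind(avail, a)
        diet <- rbind(diet, d)
        for (p in seq_len(n_plots)) {
          noise <- exp(rnorm(length(genera), 0, cover_noise_sd))
          cover <- 100 * a * noise
          survey[[length(survey) + 1L]] <- data.frame(
            grid = grids$grid[gi], plot = sprintf("P%02d", p),
            session = sessions[si], taxon = genera,
            cover = round(cover, 3),
            new_growth = state_frac[["new_growth"]],
            budding = state_frac[["budding"]],
            flowering = state_frac[["flowering"]],
            set_seed = state_frac[["set_seed"]],
            seeded = state_frac[["seeded"]],
            dead = state_frac[["dead"]],
            stringsAsFactors = FALSE)
        }
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_S%02d", grids$grid[gi],
                              format(sessions[si], "%Y%m%d"),
                              seq_len(samples_per_gs)),
          site = grids$site[gi], grid = grids$grid[gi],
          session = sessions[si],
          year = as.integer(format(sessions[si], "%Y")),
          season = seasons[si], stringsAsFactors = FALSE)
      }
    }
    rownames(avail) <- rownames(diet) <- keys
    list(survey = do.call(rbind, survey),
         metadata = do.call(rbind, meta),
         availability_truth = avail,
         diet_truth = diet,
         selection = coef)
  })
}

#' Draw genus-level diet read counts from phenology-linked truth
#'
#' Multinomial counts per fecal sample at the quantification level (skipping
#' the read-level pipeline), for fast resource-selection experiments.
#'
#' @param phen output of [generate_phenology()].
#' @param reads_per_sample expected reads per fecal sample.
#' @param seed RNG seed.
#' @return samples x genus count matrix with rownames = sample ids.
#' @export
generate_diet_counts <- function(phen, reads_per_sample = 2000L, seed = 1L) {
  meta <- phen$metadata
  key <- paste(meta$grid, format(meta$session), sep = "|")
  with_seed(seed, {
    counts <- t(vapply(seq_len(nrow(meta)), function(i) {
      p <- phen$diet_truth[key[i], ]
      as.vector(rmultinom(1L, reads_per_sample, p))
    }, numeric(ncol(phen$diet_truth))))
    dimnames(counts) <- list(meta$sample_id, colnames(phen$diet_truth))
    counts
  })
}

#' Generate a local-flora allow-list
#'
#' The allow-list mimics long-term botanical survey records: all genera that
#' can legitimately appear in diet, excluding named contaminants.
#'
#' @param ref reference database.
#' @param exclude taxa to leave off the list (synthetic contaminants).
#' @return character vector of allowed taxon labels.
#' @export
generate_allow_list <- function(ref, exclude = character(0)) {
  setdiff(unique(ref$genus), exclude)
}
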