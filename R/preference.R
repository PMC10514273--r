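#' Diet versus seed availability: resource selection
#'
#' Estimates above-ground seed availability from plant cover/phenology
#' surveys (cover-weighted sums of the flowering, set seed, seeded and
#' newly-dead state fractions), standardizes diet and availability per
#' trapping grid and session, matches the two over the surveyed taxon
#' universe (spring and summer only), and reports per-taxon selection as
#' the diet-minus-availability difference plus 10x fold-representation
#' flags and paired diversity comparisons.
#'
#' @name preference
NULL

#' Seed availability scores from a phenology survey
#'
#' For each (grid, session, taxon), the cover-weighted sum over plots of
#' the flowering + set seed + seeded + newly-dead state fractions. "Newly
#' dead" means dead in this session but not dead in the previous session of
#' the same year (seed from plants that senesced between sessions is still
#' available); the first session of a year has no previous session and
#' contributes no newly-dead fraction (recorded in the
#' "first_sessions" attribute).
#'
#' @param survey plot-level phenology data.frame with columns grid, plot,
#'   session (Date), taxon, cover, new_growth, budding, flowering,
#'   set_seed, seeded, dead.
#' @return data.frame(grid, session, taxon, score).
#' @export
seed_availability <- function(survey) {
  survey$session <- as.Date(survey$session)
  survey$year <- as.integer(format(survey$session, "%Y"))
  key <- paste(survey$grid, survey$plot, survey$taxon, survey$year, sep = "|")
  sessions_by_year <- split(survey$session, survey$year)

  # previous-session (same grid-plot-taxon-year) dead fraction
  survey$newly_dead <- 0
  first_sessions <- character(0)
  for (gr in unique(survey$grid)) {
    for (yr in unique(survey$year[survey$grid == gr])) {
      in_gy <- survey$grid == gr & survey$year == yr
      ss <- sort(unique(survey$session[in_gy]))
      first_sessions <- c(first_sessions, paste(gr, format(ss[1]), sep = "|"))
      if (length(ss) < 2) next
      for (si in 2:length(ss)) {
        cur <- which(in_gy & survey$session == ss[si])
        prv <- which(in_gy & survey$session == ss[si - 1])
        prev_dead <- survey$dead[prv][match(key[cur], key[prv])]
        alive_before <- !is.na(prev_dead) & prev_dead == 0
        survey$newly_dead[cur] <- ifelse(alive_before, survey$dead[cur], 0)
      }
    }
  }
  state_sum <- survey$flowering + survey$set_seed + survey$seeded +
    survey$newly_dead
  score <- survey$cover * state_sum
  agg <- stats::aggregate(score,
                          by = list(grid = survey$grid,
                                    session = format(survey$session),
                                    taxon = survey$taxon),
                          FUN = sum)
  names(agg)[4] <- "score"
  agg$session <- as.Date(agg$session)
  agg <- agg[order(agg$grid, agg$session, agg$taxon), ]
  rownames(agg) <- NULL
  attr(agg, "first_sessions") <- first_sessions
  agg
}

#' Standardize diet and availability per grid-session
#'
#' Diet: read counts are summed over the fecal samples of each grid-session
#' and renormalized over the shared taxon universe, which is restricted to
#' taxa observed at any time in survey plots. Availability: raw scores
#' renormalized per grid-session over the same universe. Grid-sessions with
#' zero diet reads are excluded (listed in the "excluded" attribute).
#'
#' @param diet_counts samples x taxa count matrix (genus rank).
#' @param metadata per-sample data.frame with sample_id, grid, session.
#' @param avail_scores output of [seed_availability()].
#' @return list(diet, availability): keyed "grid|session" proportion
#'   matrices over the shared taxon universe.
#' @export
standardize_grid <- function(diet_counts, metadata, avail_scores) {
  if (!all(rownames(diet_counts) %in% metadata$sample_id))
    stopf("samples missing metadata: %s",
          paste(setdiff(rownames(diet_counts), metadata$sample_id),
                collapse = ", "))
  universe <- sort(unique(avail_scores$taxon[avail_scores$score >= 0]))
  universe <- intersect(universe, colnames(diet_counts))
  if (length(universe) == 0) stopf("no taxa shared by diet and surveys")

  meta <- metadata[match(rownames(diet_counts), metadata$sample_id), ]
  key <- paste(meta$grid, format(as.Date(meta$session)), sep = "|")
  counts <- diet_counts[, universe, drop = FALSE]
  summed <- rowsum(counts, key)
  rs <- rowSums(summed)
  excluded <- rownames(summed)[rs == 0]
  summed <- summed[rs > 0, , drop = FALSE]
  diet <- summed / rowSums(summed)

  akey <- paste(avail_scores$grid, format(avail_scores$session), sep = "|")
  avail <- matrix(0, nrow = length(unique(akey)), ncol = length(universe),
                  dimnames = list(unique(akey), universe))
  for (i in seq_len(nrow(avail_scores))) {
    tx <- avail_scores$taxon[i]
    if (tx %in% universe) avail[akey[i], tx] <- avail[akey[i], tx] +
        avail_scores$score[i]
  }
  ars <- rowSums(avail)
  avail <- avail[ars > 0, , drop = FALSE] / ars[ars > 0]

  out <- list(diet = diet, availability = avail)
  attr(out, "excluded") <- excluded
  out
}

#' Match standardized diet and availability keys
#'
#' Intersects the (grid, session) keys of the two tables and removes fall
#' sessions (phenology surveys cover spring and summer only).
#'
#' @param std output of [standardize_grid()] (or a list with `diet` and
#'   `availability` keyed matrices).
#' @param seasons_kept seasons retained.
#' @return list(keys, diet, availability, taxa, season, year) - a matched
#'   set with identical key order in both matrices.
#' @export
match_samples <- function(std, seasons_kept = c("spring", "summer")) {
  keys <- intersect(rownames(std$diet), rownames(std$availability))
  dates <- as.Date(sub("^.*\\|", "", keys))
  season <- season_of_date(dates)
  keys <- keys[season %in% seasons_kept]
  if (length(keys) == 0) stopf("no matched grid-sessions after filtering")
  dropped <- setdiff(union(rownames(std$diet), rownames(std$availability)),
                     keys)
  dates <- as.Date(sub("^.*\\|", "", keys))
  out <- list(keys = keys,
              diet = std$diet[keys, , drop = FALSE],
              availability = std$availability[keys, , drop = FALSE],
              taxa = colnames(std$diet),
              season = season_of_date(dates),
              year = as.integer(format(dates, "%Y")))
  attr(out, "dropped_keys") <- dropped
  out
}

#' Selection differences (diet minus availability)
#'
#' Positive differences mean a taxon is overrepresented in diet relative to
#' its above-ground seed availability. Per-taxon seasonal and overall mean
#' differences are attached.
#'
#' @param ms matched set from [match_samples()].
#' @param flip_sign report availability - diet instead.
#' @return data.frame(key, season, year, taxon, diet, availability,
#'   difference) with attribute "taxon_means" (overall and by season).
#' @export
selection_difference <- function(ms, flip_sign = FALSE) {
  diff <- ms$diet - ms$availability
  if (flip_sign) diff <- -diff
  nk <- length(ms$keys); nt <- length(ms$taxa)
  out <- data.frame(
    key = rep(ms$keys, nt),
    season = rep(ms$season, nt),
    year = rep(ms$year, nt),
    taxon = rep(ms$taxa, each = nk),
    diet = as.vector(ms$diet),
    availability = as.vector(ms$availability),
    difference = as.vector(diff),
    stringsAsFactors = FALSE)
  overall <- colMeans(diff)
  by_season <- lapply(split(seq_len(nk), ms$season), function(i)
    colMeans(diff[i, , drop = FALSE]))
  attr(out, "taxon_means") <- c(list(overall = overall), by_season)
  out
}

#' Fold-representation flags
#'
#' A taxon in a matched key is "overrepresented" when diet exceeds `fold`
#' times availability, "underrepresented" when availability exceeds `fold`
#' times diet, otherwise "proportional". Diet with zero availability is
#' flagged "overrepresented (unavailable)" rather than an infinite fold.
#'
#' @param ms matched set.
#' @param fold fold threshold (> 1).
#' @return data.frame(key, taxon, diet, availability, fold, flag).
#' @export
fold_representation <- function(ms, fold = 10) {
  if (fold <= 1) stopf("fold must exceed 1")
  nk <- length(ms$keys); nt <- length(ms$taxa)
  diet <- as.vector(ms$diet); avail <- as.vector(ms$availability)
  ratio <- ifelse(avail > 0, diet / avail, NA_real_)
  flag <- rep("proportional", length(diet))
  flag[diet > 0 & diet > fold * avail] <- "overrepresented"
  flag[avail > 0 & avail > fold * diet] <- "underrepresented"
  flag[avail == 0 & diet > 0] <- "overrepresented (unavailable)"
  data.frame(key = rep(ms$keys, nt),
             taxon = rep(ms$taxa, each = nk),
             diet = diet, availability = avail, fold = ratio, flag = flag,
             stringsAsFactors = FALSE)
}

#' Compare diet and availability diversity over matched keys
#'
#' Shannon H' and Pielou J' are computed per matched grid-session for the
#' diet and availability rows and compared with paired t-tests; positive
#' mean differences mean diet is the more diverse/even.
#'
#' @param ms matched set.
#' @return list(per_key = data.frame of indices, H = paired test for H',
#'   J = paired test for J').
#' @export
diversity_compare <- function(ms) {
  if (length(ms$keys) < 2) stopf("need >= 2 matched keys")
  idx <- function(m) t(vapply(seq_len(nrow(m)), function(i) {
    r <- shannon_pielou(m[i, ])
    c(H = r$H, J = if (is.na(r$J)) 0 else r$J)
  }, numeric(2)))
  di <- idx(ms$diet); av <- idx(ms$availability)
  per_key <- data.frame(key = ms$keys,
                        H_diet = di[, "H"], H_avail = av[, "H"],
                        J_diet = di[, "J"], J_avail = av[, "J"],
                        stringsAsFactors = FALSE)
  list(per_key = per_key,
       H = paired_t_test(di[, "H"], av[, "H"]),
       J = paired_t_test(di[, "J"], av[, "J"]))
}
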