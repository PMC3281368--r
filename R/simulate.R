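## Synthetic spacer generator: plants tandem repeat arrays of known group
## structure inside conserved flanks, so detection, grouping and the tree
## stages can be validated by parameter recovery.  The forward substitution
## process is Jukes-Cantor, matching the distance model used downstream.

#' Simulation configuration for synthetic spacers with planted repeat arrays
#'
#' Describes a set of species-level spacer records, each carrying one tandem
#' array of repeat units drawn from a small number of group consensus
#' sequences.  Units carry conserved terminal motifs (`motif5` at the 5.8S
#' end, `motif3` at the 28S end); groups with a single planted member play
#' the role of divergent, ungrouped repeats.
#'
#' @param seed Integer seed; every stage derives its own substream from it.
#' @param species Character vector of short species codes (unit names become
#'   `<code>-<index>`).
#' @param units_per_species Integer vector, units in each species' array.
#' @param n_groups Number of distinct unit consensus sequences.
#' @param unit_pattern `"block"` (each species' array is two consecutive
#'   runs of its two groups), `"alternating"` (the two groups alternate), or
#'   a list of integer vectors giving the group index of every unit in every
#'   species.
#' @param unit_length_range Length-2 integer vector; consensus unit lengths
#'   are drawn uniformly from this range (default 95--112 nt).
#' @param group_lengths Optional integer vector of explicit per-group
#'   consensus lengths (NA entries drawn from `unit_length_range`); used to
#'   plant short units such as 74/81 nt terminal repeats.
#' @param within_group_divergence Expected JC distance between two units of
#'   the same group (must be < `between_group_divergence`; default 0.03).
#' @param between_group_divergence Expected JC distance between the
#'   consensus sequences of two different groups (default 0.2).
#' @param motif5,motif3 Conserved terminal motifs; `motif3` may use IUPAC
#'   codes (default `GGGTG` and `CAYCC`) and each group fixes one concrete
#'   expansion.
#' @param flank_lengths Length-2 integer vector, 5' and 3' conserved flank
#'   lengths standing in for the 5.8S/28S stubs plus non-repeat spacer
#'   (default 340 nt each).
#' @param background_divergence Expected JC distance between two species'
#'   non-repeat spacer (default 0.06).
#' @param species_scale Per-species multiplier on the background divergence
#'   branch (default 1 for all); used to plant one highly divergent lineage.
#' @param indel_rate Indel events per site inside unit interiors and flanks
#'   (default 0.002; lengths 1--3, never inside motifs).
#' @param isolines_per_species Number of sampled lineages per species
#'   (default 1); extra isolines diverge from the species master sequence by
#'   `within_species_divergence` without indels.
#' @param within_species_divergence Expected JC distance between two
#'   isolines of one species (default `background_divergence / 10`).
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(seed = 1L,
                       species = c("S1", "S2"),
                       units_per_species = c(3L, 3L),
                       n_groups = 2L,
                       unit_pattern = "block",
                       unit_length_range = c(95L, 112L),
                       group_lengths = NULL,
                       within_group_divergence = 0.03,
                       between_group_divergence = 0.2,
                       motif5 = "GGGTG",
                       motif3 = "CAYCC",
                       flank_lengths = c(340L, 340L),
                       background_divergence = 0.06,
                       species_scale = NULL,
                       indel_rate = 0.002,
                       isolines_per_species = 1L,
                       within_species_divergence = NULL) {
  cfg <- list(seed = as.integer(seed), species = species,
              units_per_species = as.integer(units_per_species),
              n_groups = as.integer(n_groups), unit_pattern = unit_pattern,
              unit_length_range = as.integer(unit_length_range),
              group_lengths = group_lengths,
              within_group_divergence = within_group_divergence,
              between_group_divergence = between_group_divergence,
              motif5 = toupper(motif5), motif3 = toupper(motif3),
              flank_lengths = as.integer(flank_lengths),
              background_divergence = background_divergence,
              species_scale = species_scale %||% rep(1, length(species)),
              indel_rate = indel_rate,
              isolines_per_species = as.integer(isolines_per_species),
              within_species_divergence =
                within_species_divergence %||% (background_divergence / 10))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  motif_len <- nchar(cfg$motif5) + nchar(cfg$motif3)
  if (length(cfg$units_per_species) != length(cfg$species))
    stop("units_per_species must match the number of species")
  if (any(cfg$units_per_species < 1L))
    stop("every species must carry at least one unit")
  if (cfg$n_groups < 1L) stop("n_groups must be >= 1")
  if (min(cfg$unit_length_range) < motif_len + 10L)
    stop("configuration error: unit length too short to host both motifs ",
         "(need >= ", motif_len + 10L, ")")
  if (!is.null(cfg$group_lengths)) {
    gl <- cfg$group_lengths[!is.na(cfg$group_lengths)]
    if (any(gl < motif_len + 10L))
      stop("configuration error: group length too short to host both motifs")
  }
  if (cfg$within_group_divergence >= cfg$between_group_divergence)
    stop("within_group_divergence must be < between_group_divergence")
  if (is.list(cfg$unit_pattern)) {
    if (length(cfg$unit_pattern) != length(cfg$species))
      stop("custom unit_pattern needs one vector per species")
    for (i in seq_along(cfg$species)) {
      g <- cfg$unit_pattern[[i]]
      if (length(g) != cfg$units_per_species[i])
        stop("unit_pattern[[", i, "]] length must equal units_per_species")
      if (any(g < 1L | g > cfg$n_groups))
        stop("group index out of range in unit_pattern")
    }
  } else if (!cfg$unit_pattern %in% c("block", "alternating")) {
    stop("unit_pattern must be 'block', 'alternating' or a list")
  }
  if (length(cfg$species_scale) != length(cfg$species))
    stop("species_scale must match the number of species")
  invisible(cfg)
}

## JC site-change probability giving expected estimated distance d
#' @noRd
jc_p_of_d <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Mutate a sequence to a target Jukes-Cantor distance
#'
#' Forward JC substitution: each unprotected site is replaced, with the
#' site-change probability that makes the *expected estimated* JC distance
#' between input and output equal `target_distance`, by one of the three
#' other bases chosen uniformly.  When positions are protected (e.g. the
#' terminal motifs), the change probability on the remaining sites is
#' inflated so the expectation still holds over the full sequence.
#'
#' @param sequence Nucleotide string (ACGT).
#' @param target_distance Expected substitutions/site, must satisfy
#'   `0 <= target_distance < 0.75 * unprotected_fraction` (a conservative
#'   calibration bound below the model's saturation in `p`).
#' @param seed Optional seed; when NULL the current RNG stream is used.
#' @param protect Integer vector of 1-based positions that must not mutate.
#' @return The mutated sequence (same length).
#' @export
mutate_jc <- function(sequence, target_distance, seed = NULL,
                      protect = integer(0)) {
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  if (target_distance < 0) stop("target_distance must be >= 0")
  f <- (n - length(unique(protect))) / n
  if (target_distance >= 0.75 * f)
    stop(errorCondition(
      sprintf("target_distance %.3f >= 0.75 * substitutable fraction (%.3f): JC undefined",
              target_distance, 0.75 * f),
      class = c("jc_saturation_error", "error", "condition")))
  if (target_distance == 0) return(sequence)
  p_site <- jc_p_of_d(target_distance) / f
  if (p_site >= 0.75)
    stop(errorCondition("required site-change probability reaches saturation",
                        class = c("jc_saturation_error", "error", "condition")))
  run <- function() mutate_p(sequence, p_site, protect)
  if (is.null(seed)) run() else with_seed(seed, run())
}

## Low-level: substitute each allowed site with probability p_site
#' @noRd
mutate_p <- function(sequence, p_site, protect = integer(0)) {
  chars <- seq_to_chars(sequence)
  n <- length(chars)
  allowed <- setdiff(seq_len(n), protect)
  hit <- allowed[stats::runif(length(allowed)) < p_site]
  if (length(hit)) {
    for (i in hit) chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
  }
  chars_to_seq(chars)
}

#' Draw the group consensus sequences
#'
#' Consensi are drawn as a star: a random ancestor interior is mutated
#' independently for each group so that the *pairwise* expected estimated
#' JC distance between any two consensi equals
#' `between_group_divergence` (the star branch length is solved from the
#' two-branch channel composition, with motif sites protected).  Each
#' consensus begins with `motif5` and ends with one concrete expansion of
#' `motif3`; interiors are rejected/redrawn until they contain no chance
#' occurrence of either motif, so planted unit boundaries stay identifiable.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of the config seed.
#' @return Character vector of consensus sequences named `g1..gG`, with the
#'   realized per-group lengths as attribute `"lengths"`.
#' @export
make_group_consensi <- function(config, seed = NULL) {
  cfg <- validate_sim_config(config)
  seed <- seed %||% cfg$seed
  with_seed(stage_seed(seed, "consensi"), {
    m5 <- cfg$motif5
    len5 <- nchar(m5); len3 <- nchar(cfg$motif3)
    lens <- cfg$group_lengths %||% rep(NA_integer_, cfg$n_groups)
    lens <- as.integer(lens)
    length(lens) <- cfg$n_groups
    nas <- is.na(lens)
    rng <- seq.int(cfg$unit_length_range[1], cfg$unit_length_range[2])
    lens[nas] <- rng[sample.int(length(rng), sum(nas), replace = TRUE)]
    base_len <- max(lens)
    anc_interior <- scrub_motifs_anywhere(random_dna(base_len - len5 - len3),
                                          m5, cfg$motif3)

    ## star branch: two branches compose; solve the per-branch site-change
    ## probability so the full-length pairwise expectation equals
    ## `between`.  The degenerate motif3 positions (one concrete expansion
    ## per group) contribute their own expected differences, which are
    ## counted as part of the divergence budget.
    f <- (base_len - len5 - len3) / base_len
    n_degen <- sum(lengths(IUPAC_EXPAND[seq_to_chars(cfg$motif3)]) > 1L)
    degen_p <- if (cfg$n_groups > 1L) 0.5 * n_degen / base_len else 0
    q <- (jc_p_of_d(cfg$between_group_divergence) - degen_p) / f
    if (q <= 0 || q >= 0.75)
      stop("between_group_divergence unreachable with these motif lengths")
    total_d <- -0.75 * log(1 - 4 * q / 3)
    p_branch <- jc_p_of_d(total_d / 2)

    out <- character(cfg$n_groups)
    for (g in seq_len(cfg$n_groups)) {
      interior <- mutate_p(anc_interior, p_branch)
      interior <- fit_length(interior, lens[g] - len5 - len3)
      m3 <- chars_to_seq(vapply(seq_to_chars(cfg$motif3),
                                function(ch) sample(IUPAC_EXPAND[[ch]], 1L),
                                character(1)))
      cons <- paste0(m5, interior, m3)
      cons <- scrub_interior_motifs(cons, m5, cfg$motif3)
      out[g] <- cons
    }
    names(out) <- paste0("g", seq_len(cfg$n_groups))
    attr(out, "lengths") <- nchar(out)
    out
  })
}

## shrink/grow a sequence to length L by cutting or inserting in the middle
#' @noRd
fit_length <- function(seq, L) {
  n <- nchar(seq)
  if (L == n) return(seq)
  if (L < n) {
    cut <- n - L
    at <- (n - cut) %/% 2L
    return(paste0(substr(seq, 1L, at), substr(seq, at + cut + 1L, n)))
  }
  at <- n %/% 2L
  paste0(substr(seq, 1L, at), random_dna(L - n), substr(seq, at + 1L, n))
}

## redraw bases until a bare interior holds no occurrence of either motif
#' @noRd
scrub_motifs_anywhere <- function(interior, motif5, motif3) {
  for (iter in 1:50) {
    bad <- c(motif_hits(interior, motif5), motif_hits(interior, motif3))
    if (!length(bad)) return(interior)
    chars <- seq_to_chars(interior)
    for (b in bad) {
      i <- b + 3L
      chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
    }
    interior <- chars_to_seq(chars)
  }
  stop("could not scrub chance motif occurrences")
}

## redraw bases until no internal occurrence of either terminal motif
#' @noRd
scrub_interior_motifs <- function(cons, motif5, motif3) {
  n <- nchar(cons)
  for (iter in 1:50) {
    h5 <- motif_hits(cons, motif5)
    h3 <- motif_hits(cons, motif3)
    bad5 <- h5[h5 != 0L]
    bad3 <- h3[h3 != n - nchar(motif3)]
    if (!length(bad5) && !length(bad3)) return(cons)
    chars <- seq_to_chars(cons)
    for (b in c(bad5, bad3)) {
      i <- b + 1L + (nchar(motif5) %/% 2L)   # redraw one base mid-hit
      chars[i] <- sample(setdiff(BASES, chars[i]), 1L)
    }
    cons <- chars_to_seq(chars)
  }
  stop("could not scrub chance motif occurrences")
}

## insert/delete events (length 1-3) outside protected intervals
#' @noRd
plant_indels <- function(seq, rate, protect_head = 0L, protect_tail = 0L) {
  n <- nchar(seq)
  free <- n - protect_head - protect_tail
  if (rate <= 0 || free <= 6L) return(seq)
  n_events <- stats::rbinom(1L, free, rate)
  if (n_events == 0L) return(seq)
  chars <- seq_to_chars(seq)
  for (e in seq_len(n_events)) {
    len <- sample(1:3, 1L)
    lo <- protect_head + 1L
    hi <- length(chars) - protect_tail - len
    if (hi <= lo) break
    at <- sample(seq.int(lo, hi), 1L)
    if (stats::runif(1) < 0.5) {
      chars <- append(chars, sample(BASES, len, replace = TRUE), after = at)
    } else {
      chars <- chars[-seq.int(at, at + len - 1L)]
    }
  }
  chars_to_seq(chars)
}

#' Generate a synthetic spacer dataset with ground truth
#'
#' Assembles one record per species (or per isoline) as
#' `flank5 + unit_1 ... unit_k + flank3`, where units are group consensi
#' mutated at half the within-group divergence (motifs protected) and
#' flanks descend from a common ancestor at half the background divergence
#' (optionally scaled per species).  Indels of length 1--3 are planted
#' outside motifs.  The same seed always yields byte-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of the config seed.
#' @return A `sim_dataset`: list with `records` (named uppercase sequences),
#'   `truth` (data.frame: record, species, unit index, 0-based half-open
#'   start/end, group, name), `spans` (per-record array span) and the
#'   generating `config`.
#' @export
generate_dataset <- function(config, seed = NULL) {
  cfg <- validate_sim_config(config)
  seed <- seed %||% cfg$seed
  consensi <- make_group_consensi(cfg, seed)
  len5 <- nchar(cfg$motif5); len3 <- nchar(cfg$motif3)

  with_seed(stage_seed(seed, "dataset"), {
    anc_f5 <- random_dna(cfg$flank_lengths[1])
    anc_f3 <- random_dna(cfg$flank_lengths[2])
    pw <- function(L) jc_p_of_d(cfg$within_group_divergence / 2) /
      ((L - len5 - len3) / L)

    records <- character(0)
    truth <- list(); spans <- list()
    for (s in seq_along(cfg$species)) {
      code <- cfg$species[s]
      groups <- species_groups(cfg, s)
      pbk <- jc_p_of_d(cfg$background_divergence / 2 * cfg$species_scale[s])
      f5 <- mutate_p(anc_f5, pbk)
      f3 <- mutate_p(anc_f3, pbk)
      f5 <- plant_indels(f5, cfg$indel_rate)
      f3 <- plant_indels(f3, cfg$indel_rate)
      units <- character(length(groups))
      for (u in seq_along(groups)) {
        cons <- consensi[[groups[u]]]
        L <- nchar(cons)
        prot <- c(seq_len(len5), seq.int(L - len3 + 1L, L))
        unit <- mutate_p(cons, pw(L), prot)
        units[u] <- plant_indels(unit, cfg$indel_rate, len5, len3)
      }
      master <- paste0(f5, paste(units, collapse = ""), f3)
      starts <- nchar(f5) + c(0L, cumsum(nchar(units)))[seq_along(units)]
      ends <- starts + nchar(units)
      for (iso in seq_len(cfg$isolines_per_species)) {
        rid <- if (cfg$isolines_per_species == 1L) code else
          paste0(code, "_iso", iso)
        rec <- if (iso == 1L) master else {
          prot <- unlist(lapply(seq_along(units), function(u)
            c(seq.int(starts[u] + 1L, starts[u] + len5),
              seq.int(ends[u] - len3 + 1L, ends[u]))))
          mutate_p(master, jc_p_of_d(cfg$within_species_divergence / 2), prot)
        }
        records[rid] <- rec
        truth[[length(truth) + 1L]] <- data.frame(
          record = rid, species = code, unit_index = seq_along(units),
          start = starts, end = ends, group = groups,
          name = paste0(code, "-", seq_along(units)),
          stringsAsFactors = FALSE)
        spans[[length(spans) + 1L]] <- data.frame(
          record = rid, array_start = nchar(f5),
          array_end = nchar(master) - nchar(f3), stringsAsFactors = FALSE)
      }
    }
    structure(list(records = records,
                   truth = do.call(rbind, truth),
                   spans = do.call(rbind, spans),
                   config = cfg),
              class = "sim_dataset")
  })
}

## group index of every unit of species s under the configured pattern
#' @noRd
species_groups <- function(cfg, s) {
  if (is.list(cfg$unit_pattern)) return(as.integer(cfg$unit_pattern[[s]]))
  k <- cfg$units_per_species[s]
  ga <- (2L * (s - 1L)) %% cfg$n_groups + 1L
  gb <- (2L * s - 1L) %% cfg$n_groups + 1L
  if (cfg$unit_pattern == "block") {
    c(rep(ga, ceiling(k / 2)), rep(gb, floor(k / 2)))
  } else {
    rep_len(c(ga, gb), k)
  }
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Synthetic spacer dataset:", length(x$records), "records\n")
  cnt <- table(x$truth$record)[names(x$records)]
  cat("Units per record:", paste(cnt, collapse = ", "), "\n")
  invisible(x)
}

#' Default configuration emulating the five-species repeat architecture
#'
#' A five-species setup (codes A1, A2, A3, A4, ca) with unit counts
#' 10/8/3/8/8, nine multi-member repeat groups plus seven single-member
#' (divergent) consensi, alternating two-group arrays in A4 and the
#' campestris-like species, two short terminal units (74 and 81 nt) in the
#' A3 analog, and an elevated background divergence (3x) on the A3 lineage.
#'
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
barbirostris_config <- function(...) {
  pattern <- list(
    A1 = c(1L, 2L, 6L, 1L, 2L, 6L, 1L, 2L, 6L, 10L),
    A2 = c(5L, 7L, 5L, 7L, 5L, 7L, 13L, 11L),
    A3 = c(14L, 15L, 16L),
    A4 = c(3L, 8L, 3L, 8L, 3L, 8L, 3L, 8L),
    ca = c(4L, 9L, 4L, 9L, 4L, 9L, 4L, 12L))
  lens <- rep(NA_integer_, 16L)
  lens[14L] <- 74L   # short terminal units of the A3 analog
  lens[16L] <- 81L
  defaults <- list(
    species = names(pattern),
    units_per_species = lengths(pattern),
    n_groups = 16L,
    unit_pattern = unname(pattern),
    group_lengths = lens,
    species_scale = c(1, 1, 3, 1, 1))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
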