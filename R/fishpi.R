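# piRNA -> TE seed complementarity. A piRNA "matches" a TE when the reverse
# complement of its 5' seed window occurs verbatim in the TE sequence (sense)
# or the seed itself does (antisense, i.e. complementary to the TE minus
# strand). Matching is exact: no mismatches, no G:U wobble.

#' Extract the 5' seed window of small RNAs
#'
#' The seed is the 1-based inclusive window `seed_start..seed_end` of the
#' mature 5'->3' sequence; the teleost piRNA default is positions 1-10.
#'
#' @param srnas Tibble with columns `id` and `sequence`.
#' @param seed_start,seed_end 1-based inclusive window bounds; the window
#'   must be at least `min_width` long.
#' @param min_width Floor on the window width (default 6).
#' @return `srnas` with a `seed` column appended.
#' @export
extract_seed <- function(srnas, seed_start = 1, seed_end = 10, min_width = 6) {
  if (!all(c("id", "sequence") %in% names(srnas))) {
    stop_contract("small-RNA table needs columns 'id' and 'sequence'")
  }
  if (!is_count(seed_start) || !is_count(seed_end) ||
      seed_start < 1 || seed_start > seed_end) {
    stop_contract("require 1 <= seed_start <= seed_end")
  }
  if (seed_end - seed_start + 1 < min_width) {
    stop_contract(sprintf("seed window must span at least %d nt", min_width))
  }
  short <- which(str_length(srnas$sequence) < seed_end)
  if (length(short) > 0) {
    stop_contract(sprintf(
      "sRNA '%s' is shorter (%d nt) than seed position %d",
      srnas$id[short[1]], str_length(srnas$sequence[short[1]]), seed_end
    ))
  }
  srnas <- as_tibble(srnas)
  srnas$seed <- str_sub(normalize_seq(srnas$sequence), seed_start, seed_end)
  srnas
}

#' All complementary sites of a seed in one target sequence
#'
#' Scans both orientations: sense sites are occurrences of the reverse
#' complement of the seed in the target; antisense sites are occurrences of
#' the seed itself (complementary to the target's minus strand). Overlapping
#' occurrences are all reported. Matching is exact, so seeds containing
#' ambiguity codes are rejected.
#'
#' @param seed Seed sequence (A/C/G/T only, length >= 6).
#' @param target Target nucleotide sequence (a single string).
#' @return Tibble with 0-based `position` and `orientation`
#'   (`sense`/`antisense`), ordered by position.
#' @export
seed_sites <- function(seed, target) {
  seed <- normalize_seq(seed)
  if (length(seed) != 1 || str_length(seed) < 6) {
    stop_contract("seed must be a single sequence of length >= 6")
  }
  if (str_detect(seed, "[^ACGT]")) {
    stop_contract("seed must contain only A/C/G/T (exact matching)")
  }
  target <- normalize_seq(target)
  subject <- DNAString(target)
  sense <- BiocGenerics::start(matchPattern(revcomp(seed), subject)) - 1
  antis <- BiocGenerics::start(matchPattern(seed, subject)) - 1
  tibble(
    position = c(sense, antis),
    orientation = rep(c("sense", "antisense"), c(length(sense), length(antis)))
  ) %>%
    arrange(.data$position, .data$orientation)
}

# Map raw TE class tokens onto the DNA-transposon / retroelement dichotomy.
te_class_group <- function(class) {
  dplyr::case_when(
    class %in% c("DNA", "RC", "Crypton", "DNA?", "RC?") ~ "DNA",
    class %in% c("LTR", "LINE", "SINE", "Retroposon", "RTE",
                 "LTR?", "LINE?", "SINE?") ~ "retro",
    TRUE ~ "Unknown"
  )
}

#' Label TE classes under a chosen nomenclature
#'
#' `paper` labels DNA transposons "Class I" and retroelements "Class II",
#' reproducing the labelling convention of the zebrafish sperm-sRNA study
#' this toolkit reimplements; `standard` is the conventional taxonomy
#' (Class I = retroelements with an RNA intermediate, Class II = DNA
#' transposons).
#'
#' @param class Character vector of raw class tokens (`DNA`, `LTR`, `LINE`,
#'   `SINE`, `RC`, ...).
#' @param nomenclature `"paper"` or `"standard"`.
#' @return Character vector of `Class I` / `Class II` / `Unknown` labels.
#' @export
te_class_label <- function(class, nomenclature = c("paper", "standard")) {
  nomenclature <- match.arg(nomenclature)
  group <- te_class_group(class)
  if (nomenclature == "paper") {
    dplyr::case_when(
      group == "DNA" ~ "Class I",
      group == "retro" ~ "Class II",
      TRUE ~ "Unknown"
    )
  } else {
    dplyr::case_when(
      group == "retro" ~ "Class I",
      group == "DNA" ~ "Class II",
      TRUE ~ "Unknown"
    )
  }
}

#' Match piRNA seeds against a TE reference
#'
#' For every piRNA, scans every TE sequence for exact complementary sites of
#' the 5' seed window in both orientations (see [seed_sites()]) and
#' summarises the distinct TEs matched by family and class. A TE counts once
#' per piRNA regardless of how many sites it carries; a TE matches if either
#' orientation has at least one site.
#'
#' TE identities are parsed from the FASTA headers with [parse_te_names()]
#' (RepeatMasker `name#class/family` convention); unclassifiable headers are
#' counted under class `Unknown` with a warning.
#'
#' @param pirnas Tibble of piRNAs (`id`, `sequence`), e.g. from
#'   [read_fasta()].
#' @param te_db Tibble of TE reference sequences (`id`, `sequence`).
#' @param seed_start,seed_end Seed window (1-based inclusive; default 1-10).
#' @param nomenclature Class labelling, see [te_class_label()]. The default
#'   `"paper"` is announced with a message because it inverts the
#'   conventional Class I/II taxonomy.
#' @param quiet Suppress messages.
#' @return An object of class `fishpi_result`: list with `matches` (one row
#'   per site: `srna_id`, `te_id`, `te_family`, `te_class`, `class_label`,
#'   `position`, `orientation`), `te_totals` (distinct TEs matched per
#'   piRNA), `by_class` and `by_family` summaries, and the nomenclature
#'   used.
#' @export
match_pirnas_to_tes <- function(pirnas, te_db, seed_start = 1, seed_end = 10,
                                nomenclature = c("paper", "standard"),
                                quiet = FALSE) {
  nomenclature <- match.arg(nomenclature)
  if (!is.data.frame(te_db) || nrow(te_db) == 0) {
    stop_contract("TE reference is empty")
  }
  if (!all(c("id", "sequence") %in% names(te_db))) {
    stop_contract("TE reference needs columns 'id' and 'sequence'")
  }
  if (!quiet && nomenclature == "paper") {
    inform(paste(
      "TE class nomenclature 'paper': DNA transposons are labelled Class I",
      "and retroelements Class II; use nomenclature = \"standard\" for the",
      "conventional taxonomy."
    ))
  }
  tax <- parse_te_names(te_db$id)
  if (!quiet && any(tax$class == "Unknown")) {
    warn(sprintf(
      "%d TE header(s) not classifiable as name#class/family; counted as class Unknown",
      sum(tax$class == "Unknown")
    ))
  }
  pirnas <- extract_seed(as_tibble(pirnas), seed_start, seed_end)
  te_seq <- normalize_seq(te_db$sequence)

  scan_one <- function(srna_id, seed) {
    hit_tbl <- function(pattern, orientation) {
      m <- scan_pattern(pattern, te_seq)
      if (length(m$seq_idx) == 0) return(NULL)
      idx <- m$seq_idx
      tibble(
        srna_id = srna_id,
        te_id = te_db$id[idx],
        te_family = tax$family[idx],
        te_class = tax$class[idx],
        position = m$pos0,
        orientation = orientation
      )
    }
    bind_rows(
      hit_tbl(revcomp(seed), "sense"),
      hit_tbl(seed, "antisense")
    )
  }

  matches <- map2(pirnas$id, pirnas$seed, scan_one) %>% list_rbind()
  if (nrow(matches) == 0) {
    matches <- tibble(
      srna_id = character(0), te_id = character(0),
      te_family = character(0), te_class = character(0),
      position = integer(0), orientation = character(0)
    )
  }
  matches <- matches %>%
    mutate(class_label = te_class_label(.data$te_class, nomenclature)) %>%
    arrange(.data$srna_id, .data$te_id, .data$position, .data$orientation)

  distinct_tes <- matches %>%
    distinct(.data$srna_id, .data$te_id, .keep_all = TRUE)
  te_totals <- tibble(srna_id = pirnas$id) %>%
    left_join(
      distinct_tes %>% count(.data$srna_id, name = "total_matched_tes"),
      by = "srna_id"
    ) %>%
    mutate(total_matched_tes = dplyr::coalesce(.data$total_matched_tes, 0L))
  by_class <- distinct_tes %>%
    count(.data$srna_id, .data$class_label, name = "n_tes")
  by_family <- distinct_tes %>%
    count(.data$srna_id, .data$class_label, .data$te_family, name = "n_tes")

  structure(
    list(
      matches = matches,
      te_totals = te_totals,
      by_class = by_class,
      by_family = by_family,
      nomenclature = nomenclature,
      seed_window = c(seed_start, seed_end)
    ),
    class = "fishpi_result"
  )
}

#' @export
print.fishpi_result <- function(x, ...) {
  cat(sprintf(
    "piRNA-TE complementarity: %d piRNA(s), seed window %d-%d, nomenclature '%s'\n",
    nrow(x$te_totals), x$seed_window[1], x$seed_window[2], x$nomenclature
  ))
  print(x$te_totals)
  invisible(x)
}

#' @rdname match_pirnas_to_tes
#' @param x A `fishpi_result`.
#' @param ... Unused.
#' @export
tidy.fishpi_result <- function(x, ...) x$matches

#' @rdname match_pirnas_to_tes
#' @export
glance.fishpi_result <- function(x, ...) {
  tibble(
    n_srnas = nrow(x$te_totals),
    n_matched_tes = sum(x$te_totals$total_matched_tes),
    n_sites = nrow(x$matches),
    nomenclature = x$nomenclature
  )
}

#' Plot-ready class/family chart table
#'
#' Flattens a [match_pirnas_to_tes()] summary into one table of distinct-TE
#' counts per (piRNA, class, family), sorted by count descending; totals are
#' conserved with respect to `te_totals`.
#'
#' @param result A `fishpi_result`.
#' @return Tibble `srna_id`, `class_label`, `te_family`, `n_tes`.
#' @export
summarize_class_chart <- function(result) {
  if (!inherits(result, "fishpi_result")) {
    stop_contract("expected a fishpi_result")
  }
  result$by_family %>%
    select("srna_id", "class_label", "te_family", "n_tes") %>%
    arrange(desc(.data$n_tes), .data$srna_id, .data$te_family)
}

#' @rdname match_pirnas_to_tes
#' @param object A `fishpi_result`.
#' @export
autoplot.fishpi_result <- function(object, ...) {
  dat <- object$by_class
  ggplot(dat, aes(x = .data$class_label, y = .data$n_tes,
                  fill = .data$class_label)) +
    geom_col() +
    facet_wrap(~srna_id) +
    labs(
      x = "TE class", y = "complementary TEs (distinct)",
      title = "TEs complementary to piRNA seed regions",
      fill = "TE class"
    ) +
    theme_minimal()
}
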