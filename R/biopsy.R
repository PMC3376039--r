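#' Default biopsy-needle gauge table
#'
#' Nominal internal diameters (mm) of regular-wall needles by gauge number,
#' following the ISO 9626 nominal dimensions. The gauge number is what
#' pathology reports record; the internal diameter sets the width of the
#' tissue core and hence the cortex area of a section. The table is plain
#' configuration: replace or extend it to match the needles actually used.
#'
#' @return a named numeric vector, names = gauge numbers, values = internal
#'   diameter in millimetres (in-vivo scale; the core width before
#'   shrinkage).
#' @export
default_gauge_table <- function() {
  c(`14` = 1.60, `15` = 1.37, `16` = 1.19, `17` = 1.07, `18` = 0.84,
    `19` = 0.69, `20` = 0.60, `21` = 0.51, `22` = 0.41)
}

#' Internal diameter of a biopsy needle
#'
#' @param gauge integer gauge number.
#' @param table named numeric vector mapping gauge numbers to internal
#'   diameters in mm; default [default_gauge_table()].
#' @return internal diameter `d_b`, mm.
#' @export
needle_internal_diameter <- function(gauge, table = default_gauge_table()) {
  if (length(gauge) != 1L || is.na(gauge))
    stop_lookup("gauge must be a single non-missing value")
  key <- as.character(as.integer(gauge))
  if (!key %in% names(table))
    stop_lookup("unknown needle gauge ", key, "; known gauges: ",
                paste(names(table), collapse = ", "))
  unname(table[[key]])
}

#' One biopsy section
#'
#' Cortex segment lengths are measured on the slide (mm), from the
#' outermost to the innermost glomerulus; when the medulla is sandwiched
#' between cortices the section carries two (or more) segments and their
#' total is the cortex length of the section.
#'
#' @param cortex_segment_lengths numeric vector of segment lengths, mm,
#'   on-slide scale.
#' @param n_glomeruli number of glomerular profiles observed in the section.
#' @param n_global_sclerosis number of those with global sclerosis.
#' @return an object of class `biopsy_section`.
#' @export
biopsy_section <- function(cortex_segment_lengths, n_glomeruli,
                           n_global_sclerosis = 0L) {
  if (!is.numeric(cortex_segment_lengths) ||
      any(!is.finite(cortex_segment_lengths)) ||
      any(cortex_segment_lengths < 0))
    stop_domain("cortex_segment_lengths must be finite and >= 0")
  n_glomeruli <- as.integer(n_glomeruli)
  n_global_sclerosis <- as.integer(n_global_sclerosis)
  if (is.na(n_glomeruli) || n_glomeruli < 0L)
    stop_domain("n_glomeruli must be a count >= 0")
  if (is.na(n_global_sclerosis) || n_global_sclerosis < 0L)
    stop_domain("n_global_sclerosis must be a count >= 0")
  if (n_global_sclerosis > n_glomeruli)
    stop_domain("n_global_sclerosis (", n_global_sclerosis,
                ") cannot exceed n_glomeruli (", n_glomeruli, ")")
  structure(
    list(cortex_segment_lengths = as.numeric(cortex_segment_lengths),
         n_glomeruli = n_glomeruli,
         n_global_sclerosis = n_global_sclerosis),
    class = "biopsy_section"
  )
}

#' A biopsy specimen: one or more sections plus the needle gauge
#'
#' @param sections list of [biopsy_section()] objects (a single section may
#'   be given bare).
#' @param needle_gauge integer gauge number of the biopsy needle.
#' @param stain staining label, informational ("PAS", "PAM-HE", ...).
#' @return an object of class `biopsy_specimen`.
#' @export
biopsy_specimen <- function(sections, needle_gauge, stain = "PAS") {
  if (inherits(sections, "biopsy_section")) sections <- list(sections)
  if (!is.list(sections) || length(sections) == 0L ||
      !all(vapply(sections, inherits, logical(1), "biopsy_section")))
    stop_domain("sections must be a non-empty list of biopsy_section objects")
  needle_gauge <- as.integer(needle_gauge)
  if (is.na(needle_gauge)) stop_domain("needle_gauge must be an integer")
  structure(
    list(sections = sections, needle_gauge = needle_gauge,
         stain = as.character(stain)[1]),
    class = "biopsy_specimen"
  )
}

#' @export
print.biopsy_specimen <- function(x, ...) {
  n <- vapply(x$sections, `[[`, integer(1), "n_glomeruli")
  len <- vapply(x$sections, function(s) sum(s$cortex_segment_lengths),
                numeric(1))
  cat(sprintf(
    "Biopsy specimen: %d section(s), %dG needle, stain %s\n",
    length(x$sections), x$needle_gauge, x$stain))
  cat(sprintf("  glomeruli per section: %s (total %d)\n",
              paste(n, collapse = ", "), sum(n)))
  cat(sprintf("  cortex length per section (mm, on slide): %s\n",
              paste(format(len, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Apply the section-usability and specimen-adequacy rules
#'
#' A section containing exactly one glomerulus is ignored entirely (its
#' profile count and its cortex length are both dropped). The specimen is
#' flagged `insufficient` when the total glomerular count over all obtained
#' sections -- including any ignored ones -- is under 8. The adequacy flag
#' never suppresses downstream estimates; it travels with them.
#'
#' @param specimen a [biopsy_specimen()].
#' @return a list with `usable` (logical vector over sections), `n_s`
#'   (total observed glomeruli over retained sections), `n_sclerotic`
#'   (globally sclerotic among them), `sections_ignored` (count), and
#'   `adequate` (logical).
#' @examples
#' sp <- biopsy_specimen(list(
#'   biopsy_section(5, 1), biopsy_section(6, 5), biopsy_section(7, 4)), 16)
#' assess_adequacy(sp)  # first section ignored, N_s = 9, adequate
#' @export
assess_adequacy <- function(specimen) {
  if (!inherits(specimen, "biopsy_specimen"))
    stop_domain("specimen must be a biopsy_specimen")
  counts <- vapply(specimen$sections, `[[`, integer(1), "n_glomeruli")
  scler <- vapply(specimen$sections, `[[`, integer(1), "n_global_sclerosis")
  usable <- counts != 1L
  list(
    usable = usable,
    n_s = sum(counts[usable]),
    n_sclerotic = sum(scler[usable]),
    sections_ignored = sum(!usable),
    adequate = sum(counts) >= 8L
  )
}

#' In-vivo cortex area of a biopsy specimen
#'
#' The gross cortex area sampled by the needle is the total cortex length
#' times the internal needle diameter, `A_cortex_s = L_{a+b} * d_b`.
#' On-slide lengths are first corrected to in-vivo scale by the tissue
#' linear shrinkage factor; the needle diameter is already an in-vivo
#' dimension. Only usable sections (see [assess_adequacy()]) contribute
#' length.
#'
#' @param specimen a [biopsy_specimen()].
#' @param shrinkage a [shrinkage_model()]; default `shrinkage_model()`.
#' @param table gauge table, see [needle_internal_diameter()].
#' @return cortex area `A_cortex_s` in square micrometres (in-vivo scale).
#' @export
cortex_section_area <- function(specimen, shrinkage = shrinkage_model(),
                                table = default_gauge_table()) {
  if (!inherits(specimen, "biopsy_specimen"))
    stop_domain("specimen must be a biopsy_specimen")
  if (!inherits(shrinkage, "shrinkage_model"))
    stop_domain("shrinkage must be a shrinkage_model")
  adeq <- assess_adequacy(specimen)
  lengths_mm <- vapply(specimen$sections,
                       function(s) sum(s$cortex_segment_lengths), numeric(1))
  total_mm <- sum(lengths_mm[adeq$usable])
  if (total_mm <= 0)
    stop_domain("no usable cortex length in specimen")
  d_b <- needle_internal_diameter(specimen$needle_gauge, table)
  l_vivo_mm <- correct_to_in_vivo(total_mm, shrinkage$linear_factor_tissue)
  # mm^2 -> um^2
  l_vivo_mm * d_b * 1e6
}
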