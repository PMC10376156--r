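# Standard anthropometric fractions (Winter, "Biomechanics and Motor
# Control of Human Movement", Table 4.1): segment mass as a fraction of
# body mass, segment length as a fraction of height, centre of mass as a
# fraction of segment length from the proximal end, and radius of gyration
# about the COM as a fraction of segment length.
.anthro_table <- data.frame(
  segment   = c("thigh", "shank", "foot"),
  length_h  = c(0.245, 0.246, 0.152),
  mass_m    = c(0.100, 0.0465, 0.0145),
  com_frac  = c(0.433, 0.433, 0.500),
  rg_frac   = c(0.323, 0.302, 0.475)
)

#' Subject anthropometrics
#'
#' Builds the rigid-segment parameter set (lengths, masses, centre-of-mass
#' and radius-of-gyration fractions for thigh, shank, foot) from height and
#' body mass using standard published fractions.
#'
#' @param height_m standing height in metres.
#' @param mass_kg body mass in kilograms.
#' @param id optional subject identifier.
#' @return A `subject` list with `height_m`, `mass_kg`, `id` and a
#'   `segments` data frame (`segment`, `length_m`, `mass_kg`, `com_frac`,
#'   `rg_frac`).
#' @export
subject <- function(height_m, mass_kg, id = NA_character_) {
  stopifnot(height_m > 0, mass_kg > 0)
  seg <- .anthro_table
  segments <- data.frame(segment = seg$segment,
                         length_m = seg$length_h * height_m,
                         mass_kg = seg$mass_m * mass_kg,
                         com_frac = seg$com_frac,
                         rg_frac = seg$rg_frac)
  structure(list(height_m = height_m, mass_kg = mass_kg, id = id,
                 segments = segments),
            class = "subject")
}

#' Sample a subject from the cohort distribution
#'
#' Height ~ Normal(1.74, 0.08) m and mass ~ Normal(81.6, 19.5) kg (truncated
#' to positive values), matching the healthy stair-ascent cohort statistics;
#' segment parameters follow via [subject()].
#'
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param id optional subject identifier.
#' @return A [subject()].
#' @export
sample_subject <- function(seed = NULL, id = NA_character_) {
  if (!is.null(seed)) set.seed(seed)
  h <- 0
  while (h <= 0.5) h <- stats::rnorm(1, 1.74, 0.08)
  m <- 0
  while (m <= 1) m <- stats::rnorm(1, 81.6, 19.5)
  subject(h, m, id = id)
}

seg_par <- function(subj, name) {
  i <- match(name, subj$segments$segment)
  as.list(subj$segments[i, ])
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf("<subject%s> height %.2f m, mass %.1f kg\n",
              if (is.na(x$id)) "" else paste0(" ", x$id),
              x$height_m, x$mass_kg))
  invisible(x)
}
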