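#' Declare a candidate signaling cascade
#'
#' A cascade is an ordered list of phosphorylation steps. A step may list
#' alternative molecules (a branch), e.g. `MKK4|MKK3` in the
#' stress-responsive ASK1-MKK4/MKK3-JNK cascade; consecutive steps then
#' contribute one edge per branch combination.
#'
#' @param name Short cascade name (e.g. `"SRME"`, `"AMMJ"`).
#' @param steps Either a character vector of molecule ids (`"A|B"` marks
#'   alternatives) or a list of character vectors.
#' @return An object of class `"cascade_spec"` with the steps and the
#'   derived edge table.
#' @export
cascade_spec <- function(name, steps) {
  if (is.character(steps)) steps <- strsplit(steps, "|", fixed = TRUE)
  stopifnot(length(steps) >= 2, all(lengths(steps) >= 1))
  edges <- dplyr::bind_rows(purrr::map(seq_len(length(steps) - 1), function(i) {
    tidyr::expand_grid(from = steps[[i]], to = steps[[i + 1]])
  }))
  structure(list(name = name, steps = steps, edges = edges),
            class = "cascade_spec")
}

#' @export
print.cascade_spec <- function(x, ...) {
  cat("<cascade_spec> ", x$name, ": ",
      paste(purrr::map_chr(x$steps, paste, collapse = "|"), collapse = " -> "),
      " (", nrow(x$edges), " edges)\n", sep = "")
  invisible(x)
}

#' Noise floor from negative-control STRs
#'
#' The activation floor is the maximal STR measured on negative-control
#' (antibody-free) array spots run through the same duration/STR pipeline
#' as real molecules. A molecule whose mean STR does not exceed this floor
#' cannot be distinguished from array noise. Negative-control series with
#' no detectable signal contribute nothing; if none has a measurable STR
#' the floor is 0, with a warning.
#'
#' @param negctrl_strs Numeric vector of negative-control STRs (1/min);
#'   `NA` entries mark series with no signal.
#' @return Scalar floor (1/min).
#' @export
noise_floor <- function(negctrl_strs) {
  if (length(negctrl_strs) == 0) {
    stop("no negative-control STR values; supply a manual floor", call. = FALSE)
  }
  vals <- negctrl_strs[!is.na(negctrl_strs)]
  if (length(vals) == 0) {
    warning("all negative-control series had no signal; noise floor set to 0",
            call. = FALSE)
    return(0)
  }
  max(vals)
}

#' Decide whether a cascade is activated
#'
#' A cascade is called activated when (a) every consecutive edge — for
#' branched steps, every branch edge — has STRs judged similar, and (b)
#' every step's EAP STR exceeds the noise floor. Both ingredients are
#' reported: `failing_edges` lists edges whose STRs differ, `below_floor`
#' the molecules indistinguishable from noise.
#'
#' @param spec A [cascade_spec()].
#' @param posteriors Named list of `posterior_summary` objects covering all
#'   molecules in the cascade.
#' @param assessments Tibble of pairwise assessments (from [assess_pair()])
#'   with columns `molecule_a`, `molecule_b`, `similar`, covering every edge
#'   in either orientation.
#' @param floor Noise floor in 1/min (see [noise_floor()]).
#' @return A list of class `"cascade_call"`: `name`, `activated`,
#'   `failing_edges` (character, `"A-B"`), `below_floor` (character),
#'   `noise_floor`.
#' @export
assess_cascade <- function(spec, posteriors, assessments, floor) {
  stopifnot(inherits(spec, "cascade_spec"), is.numeric(floor))
  mols <- unique(unlist(spec$steps))
  missing_post <- setdiff(mols, names(posteriors))
  if (length(missing_post)) {
    stop("no posterior for molecule(s): ", paste(missing_post, collapse = ", "),
         call. = FALSE)
  }
  edge_similar <- purrr::map_lgl(seq_len(nrow(spec$edges)), function(i) {
    a <- spec$edges$from[i]; b <- spec$edges$to[i]
    hit <- (assessments$molecule_a == a & assessments$molecule_b == b) |
      (assessments$molecule_a == b & assessments$molecule_b == a)
    if (!any(hit)) {
      stop(sprintf("no similarity assessment for edge %s-%s", a, b),
           call. = FALSE)
    }
    all(assessments$similar[hit])
  })
  failing <- sprintf("%s-%s", spec$edges$from, spec$edges$to)[!edge_similar]
  eaps <- purrr::map_dbl(mols, ~ posteriors[[.x]]$eap_mu)
  below <- mols[eaps <= floor]
  structure(
    list(name = spec$name,
         activated = length(failing) == 0 && length(below) == 0,
         failing_edges = failing, below_floor = below, noise_floor = floor),
    class = "cascade_call"
  )
}

#' @export
print.cascade_call <- function(x, ...) {
  cat(sprintf("<cascade_call> %s: %s (floor %.3g/min)\n", x$name,
              if (x$activated) "ACTIVATED" else "not activated", x$noise_floor))
  if (length(x$failing_edges)) {
    cat("  dissimilar edges:", paste(x$failing_edges, collapse = ", "), "\n")
  }
  if (length(x$below_floor)) {
    cat("  below noise floor:", paste(x$below_floor, collapse = ", "), "\n")
  }
  invisible(x)
}
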