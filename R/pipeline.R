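# Full analysis chain: recording + annotations -> per-eye deviation records.

#' Analyze a recording end to end
#'
#' Runs the complete chain for both events: slice the LE-test and RE-test
#' intervals, detect per-target dwells of the fixating eye, estimate each
#' eye's fixation per dwell, and convert to signed prismatic deviation
#' records.
#'
#' @param recording a [gaze_recording()]
#' @param annotations an [event_annotations()] object
#' @param grid a `target_grid`
#' @param geometry a [screen_geometry()]
#' @param params a [dwell_params()]
#' @param central_only restrict records to the nine central targets
#' @param min_valid_floor quality floor on per-eye valid sample counts
#' @param center robust center for fixation estimates (`"median"` or `"mean"`)
#' @param order traversal order actually followed (default: the grid's)
#' @return a `deviation_records` data.frame covering both tested eyes
#' @export
analyze_recording <- function(recording, annotations,
                              grid = build_target_grid(),
                              geometry = screen_geometry(),
                              params = dwell_params(),
                              central_only = TRUE, min_valid_floor = 10,
                              center = "median", order = NULL) {
  per_eye <- lapply(c("LE", "RE"), function(eye) {
    slice <- slice_event(recording, annotations, eye)
    dwells <- detect_dwells(slice, grid, params, order = order)
    estimates <- lapply(seq_len(nrow(dwells)), function(i)
      estimate_fixation(slice, dwells[i, ], center = center))
    build_records(estimates, tested_eye = eye,
                  subject_id = recording$subject_id, geometry = geometry,
                  central_only = central_only,
                  min_valid_floor = min_valid_floor, grid = grid)
  })
  out <- do.call(rbind, per_eye)
  class(out) <- c("deviation_records", "data.frame")
  out
}

#' Analyze a simulated cohort
#'
#' Convenience wrapper running [analyze_recording()] over a
#' [simulate_cohort()] bundle and row-binding the records.
#'
#' @param cohort an `hlst_cohort`
#' @param ... passed to [analyze_recording()]
#' @return a `deviation_records` data.frame with one block per subject
#' @export
analyze_cohort <- function(cohort, ...) {
  out <- do.call(rbind, lapply(cohort, function(subj)
    analyze_recording(subj$recording, subj$annotations, ...)))
  class(out) <- c("deviation_records", "data.frame")
  out
}
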