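## Plain-text file dialects: tab-separated event tables (one file per
## subject-session), two-column respiration CSVs with a sampling-rate
## sidecar, flat-table serialisation of beta pattern sets, and distance
## summary CSVs. Optional NIfTI export of voxel volumes and masks.

#' Write / read an event table (TSV)
#'
#' Columns: onset, duration, trial_type (odor), category, catch (0/1),
#' run, session, subject, group.
#'
#' @param events event table (one subject-session)
#' @param path file path
#' @return `readEventTable` returns the event table with the in-memory
#'   column names
#' @export
writeEventTable <- function(events, path) {
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = events$odor, category = events$category,
                    catch = as.integer(events$catch), run = events$run,
                    session = events$session, subject = events$subject,
                    group = events$group)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(onset = d$onset, duration = d$duration, odor = d$trial_type,
             category = d$category, catch = d$catch != 0L, run = d$run,
             trial = stats::ave(d$onset, d$run, FUN = seq_along),
             session = d$session, subject = d$subject, group = d$group,
             stringsAsFactors = FALSE)
}

#' Write / read a respiration trace (CSV plus sampling-rate sidecar)
#'
#' @param trace a `SniffTrace`
#' @param path CSV path (`time`, `flow`); a `<path>.meta` sidecar stores
#'   the sampling rate
#' @export
writeRespirationTrace <- function(trace, path) {
  utils::write.csv(data.frame(time = trace$time, flow = trace$flow),
                   path, row.names = FALSE)
  writeLines(paste0("sampling_rate=", trace$sampling_rate),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname writeRespirationTrace
#' @export
readRespirationTrace <- function(path) {
  d <- utils::read.csv(path)
  meta <- readLines(paste0(path, ".meta"))
  fs <- as.numeric(sub("sampling_rate=", "", meta[1L]))
  structure(list(time = d$time, flow = d$flow, sampling_rate = fs,
                 truth = NULL),
            class = "SniffTrace")
}

#' Serialise / read a BetaPatternSet as a flat table
#'
#' Long CSV with columns subject, session, group, roi, odor, run,
#' voxel_index, hemisphere, value.
#'
#' @param x a [BetaPatternSet-class]
#' @param path CSV path
#' @export
writeBetaPatternSet <- function(x, path) {
  md <- S4Vectors::metadata(x)
  info <- patternInfo(x)
  B <- betaMatrix(x)
  hem <- hemisphereLabels(x)
  long <- data.frame(subject = md$subject, session = md$session,
                     group = md$group, roi = md$roi,
                     odor = rep(info$odor, each = nrow(B)),
                     category = rep(info$category, each = nrow(B)),
                     run = rep(info$run, each = nrow(B)),
                     voxel_index = rep(seq_len(nrow(B)), ncol(B)),
                     hemisphere = rep(hem, ncol(B)),
                     value = as.vector(B))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBetaPatternSet
#' @export
readBetaPatternSet <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  nv <- max(d$voxel_index)
  key <- paste(d$odor, d$run)
  ukey <- unique(key)
  B <- vapply(ukey, function(k) d$value[key == k], numeric(nv))
  first <- match(ukey, key)
  BetaPatternSet(B, odor = d$odor[first], category = d$category[first],
                 run = d$run[first],
                 hemisphere = d$hemisphere[seq_len(nv)],
                 subject = d$subject[1L], session = d$session[1L],
                 group = d$group[1L], roi = d$roi[1L],
                 normalized = TRUE)
}

#' Write a distance summary table (CSV)
#'
#' @param summaries data.frame with subject, group, session, roi, same,
#'   within, across, adj_within, adj_across
#' @param path CSV path
#' @export
writeDistanceSummary <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}

#' Export run volumes and an ROI mask as NIfTI
#'
#' Optional heavyweight export: voxels are laid out along one axis of a
#' 4-D volume (x = voxel, t = scan) and the mask encodes hemisphere in
#' label parity (odd = left, even = right). Requires the RNifti package.
#'
#' @param bold n_scans x n_voxels matrix
#' @param hemisphere per-voxel "L"/"R" labels
#' @param path output prefix; writes `<path>_bold.nii.gz` and
#'   `<path>_mask.nii.gz`
#' @export
writeNiftiVolumes <- function(bold, hemisphere, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("NIfTI export requires the RNifti package")
  }
  nv <- ncol(bold)
  vol <- array(t(bold), dim = c(nv, 1L, 1L, nrow(bold)))
  RNifti::writeNifti(vol, paste0(path, "_bold.nii.gz"))
  mask <- array(ifelse(hemisphere == "L", 1L, 2L), dim = c(nv, 1L, 1L))
  RNifti::writeNifti(mask, paste0(path, "_mask.nii.gz"))
  invisible(path)
}

#' Validate input files against the package's dialects
#'
#' Schema checks for event TSVs and ratings CSVs: required columns, label
#' sets, monotone onsets within run, catch flags. Returns a report rather
#' than failing.
#'
#' @param events_paths character vector of event TSV paths
#' @param ratings_paths character vector of ratings CSV paths (descriptor
#'   tables with odor, descriptor, rating)
#' @param masks optional named list of per-voxel hemisphere label vectors
#'   ("L"/"R"); a mask must be nonempty in both hemispheres
#' @return data.frame: file, violation (zero rows when everything checks
#'   out)
#' @export
validateInputs <- function(events_paths = character(0L),
                           ratings_paths = character(0L),
                           masks = list()) {
  bad <- list()
  note <- function(f, msg) bad[[length(bad) + 1L]] <<-
    data.frame(file = f, violation = msg, stringsAsFactors = FALSE)
  for (f in events_paths) {
    d <- tryCatch(utils::read.delim(f, stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(d)) { note(f, "unreadable TSV"); next }
    need <- c("onset", "duration", "trial_type", "category", "catch",
              "run", "session", "subject", "group")
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      note(f, paste("missing columns:", paste(miss, collapse = ", ")))
      next
    }
    for (r in unique(d$run)) {
      if (is.unsorted(d$onset[d$run == r])) {
        note(f, paste0("non-monotone onsets in run ", r))
      }
    }
    if (!all(d$catch %in% c(0L, 1L))) note(f, "catch flags not 0/1")
    if (any(d$duration <= 0)) note(f, "non-positive durations")
  }
  for (f in ratings_paths) {
    d <- tryCatch(utils::read.csv(f, stringsAsFactors = FALSE),
                  error = function(e) NULL)
    if (is.null(d)) { note(f, "unreadable CSV"); next }
    need <- c("odor", "descriptor", "rating")
    miss <- setdiff(need, names(d))
    if (length(miss)) {
      note(f, paste("missing columns:", paste(miss, collapse = ", ")))
      next
    }
    if (any(!is.finite(d$rating))) note(f, "non-finite ratings")
  }
  for (m in seq_along(masks)) {
    nm <- if (!is.null(names(masks))) names(masks)[m] else
      paste0("mask", m)
    hem <- masks[[m]]
    if (!all(hem %in% c("L", "R"))) {
      note(nm, "hemisphere labels must be 'L'/'R'")
    } else if (!all(c("L", "R") %in% hem)) {
      note(nm, paste("empty hemisphere:",
                     paste(setdiff(c("L", "R"), unique(hem)),
                           collapse = ", ")))
    }
  }
  if (length(bad) == 0L) {
    return(data.frame(file = character(0L), violation = character(0L)))
  }
  do.call(rbind, bad)
}
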