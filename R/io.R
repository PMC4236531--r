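#' Read an OpenSim-style STO/MOT time-series file
#'
#' Tab-delimited text with a header terminated by `endheader` and a first
#' column named `time`.  Units are whatever the writer used; the shipped
#' writers use SI (s, rad, Nm).
#'
#' @param path file path.
#' @return data.frame with a `time` column; header key-value pairs are kept
#'   in the `"sto_header"` attribute.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", trimws(lines))
  if (is.na(end)) stop("not an STO/MOT file: no 'endheader' line")
  header <- lines[seq_len(end - 1L)]
  df <- read.table(text = lines[-seq_len(end)], header = TRUE, sep = "\t",
                   check.names = FALSE)
  if (tolower(names(df)[1]) != "time") stop("first STO column must be 'time'")
  names(df)[1] <- "time"
  attr(df, "sto_header") <- header
  df
}

#' Write an OpenSim-style STO/MOT file
#'
#' @param df data.frame whose first column is `time`.
#' @param path output path.
#' @param name dataset name written in the header.
#' @return invisibly, `path`.
#' @export
write_sto <- function(df, path, name = "capgap") {
  if (tolower(names(df)[1]) != "time") stop("first column must be 'time'")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name, "version=1",
               sprintf("nRows=%d", nrow(df)),
               sprintf("nColumns=%d", ncol(df)),
               "inDegrees=no", "endheader",
               paste(names(df), collapse = "\t")), con)
  write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a trial to STO (kinematics + moments)
#'
#' Columns: time, `<dof>_angle` (rad), `<dof>_velocity` (rad/s),
#' `<dof>_moment` (Nm).
#'
#' @param trial a [trial_data()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trial_sto <- function(trial, path) {
  df <- data.frame(time = trial$time,
                   setNames(as.data.frame(trial$angles),
                            paste0(colnames(trial$angles), "_angle")),
                   setNames(as.data.frame(trial$angular_velocities),
                            paste0(colnames(trial$angular_velocities), "_velocity")),
                   setNames(as.data.frame(trial$net_moments),
                            paste0(colnames(trial$net_moments), "_moment")),
                   check.names = FALSE)
  write_sto(df, path, name = paste0("capgap_trial_", trial$activity))
}

#' Read a trial from a capgap trial STO file
#'
#' Counterpart of [write_trial_sto()].
#'
#' @param path STO file path.
#' @param activity activity label of the trial.
#' @param body_mass body mass (kg).
#' @return a [trial_data()].
#' @export
read_trial_sto <- function(path, activity, body_mass) {
  df <- read_sto(path)
  pick <- function(suffix) {
    cols <- grep(paste0("_", suffix, "$"), names(df), value = TRUE)
    m <- as.matrix(df[cols])
    colnames(m) <- sub(paste0("_", suffix, "$"), "", cols)
    m
  }
  trial_data(activity = activity, time = df$time,
             angles = pick("angle"), angular_velocities = pick("velocity"),
             net_moments = pick("moment"), body_mass = body_mass)
}

#' Export per-frame solutions as STO or CSV
#'
#' Columns: time, one per muscle activation, one per reserve activation and
#' one per reserve moment.
#'
#' @param solutions a `trial_solution`.
#' @param trial the matching [trial_data()].
#' @param path output path.
#' @param format `"sto"` or `"csv"`.
#' @return invisibly, `path`.
#' @export
write_solution <- function(solutions, trial, path, format = c("sto", "csv")) {
  format <- match.arg(format)
  df <- data.frame(time = trial$time,
                   solutions$muscle_activations,
                   setNames(as.data.frame(solutions$reserve_activations),
                            paste0("reserve_", colnames(solutions$reserve_activations))),
                   setNames(as.data.frame(solutions$reserve_moments),
                            paste0("reserve_moment_", colnames(solutions$reserve_moments))),
                   check.names = FALSE)
  if (format == "sto") write_sto(df, path, "capgap_static_optimization")
  else write.csv(df, path, row.names = FALSE)
  invisible(path)
}
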