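#!/usr/bin/env Rscript
# Learning-job worker: executes one job directory and records its outcome.
# Invoked by the service as: Rscript run_job.R <job_dir>

suppressPackageStartupMessages(library(voxelearn))

args <- commandArgs(trailingOnly = TRUE)
job_dir <- args[[1]]

read_job <- function() jsonlite::fromJSON(file.path(job_dir, "job.json"))
write_job <- function(job) jsonlite::write_json(
  job, file.path(job_dir, "job.json"), auto_unbox = TRUE, digits = NA,
  null = "null")

input_path <- function(filename) {
  files <- jsonlite::fromJSON(file.path(job_dir, "files.json"))
  row <- files[files$filename == filename & files$role == "input", ]
  if (nrow(row) == 0L) stop("missing input file: ", filename)
  file.path(job_dir, "input", paste0(row$file_id[1], "_", filename))
}

register_output <- function(src, filename) {
  files <- jsonlite::fromJSON(file.path(job_dir, "files.json"))
  file_id <- sprintf("file-%03d", nrow(files) + 1L)
  file.copy(src, file.path(job_dir, "output", paste0(file_id, "_", filename)))
  files <- rbind(files, data.frame(file_id = file_id, role = "output",
                                   filename = filename,
                                   size = file.info(src)$size))
  jsonlite::write_json(files, file.path(job_dir, "files.json"), digits = NA)
}

job <- read_job()
status <- tryCatch({
  req <- jsonlite::fromJSON(input_path("request.json"))
  if (identical(job$learning_type, "train")) {
    tt <- read_training_json(input_path("features.json"))
    model <- if (identical(req$model, "strong")) {
      train_strong(tt$x, tt$y, seed = req$seed)
    } else {
      train_classifier(
        classifier_spec(req$model, as.list(req$hyperparameters),
                        seed = req$seed),
        tt$x, tt$y)
    }
    out <- file.path(job_dir, "model_tmp.vxl")
    save_model(model, out)
    register_output(out, "model.vxl")
    unlink(out)
  } else if (identical(job$learning_type, "infer")) {
    model <- load_model(input_path("model.vxl"))
    vol <- read_volume(input_path(req$volume_filename))
    bank <- if (!is.null(req$bank_filename))
      read_feature_bank(input_path(req$bank_filename))
    else feature_bank_default()
    pm <- infer_volume(model, vol, bank,
                       block_shape = req$block_shape)
    out <- file.path(job_dir, "prob_tmp.tif")
    write_volume(pm, out, format = "tiff")
    register_output(out, "probability.tif")
    unlink(out)
  } else {
    stop("unknown learning type: ", job$learning_type)
  }
  "done"
}, error = function(e) {
  job <- read_job()
  job$error_message <- conditionMessage(e)
  write_job(job)
  "error"
})

job <- read_job()
job$status <- status
write_job(job)
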