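#' Start a learning-job service
#'
#' A directory-backed job service mirroring the remote-learning workflow:
#' jobs are created, input files uploaded, a learning run launched, the
#' status polled until `done` (or `error`), and output files downloaded.
#' Job state lives under `root`, one directory per job, so concurrent
#' jobs are fully isolated. Launched jobs run asynchronously in a
#' separate R worker process; given identical inputs and seeds the worker
#' produces bit-identical results to a local run.
#'
#' The job lifecycle is `created -> running -> done | error` (`created`
#' is the initial state in which uploads are accepted; a launched job can
#' no longer receive files).
#'
#' @param root Directory for job state (created if missing).
#' @return An object of class `voxel_service`.
#' @export
voxel_service <- function(root = tempfile("voxel_service_")) {
  dir.create(file.path(root, "jobs"), recursive = TRUE, showWarnings = FALSE)
  structure(list(root = normalizePath(root)), class = "voxel_service")
}

#' @export
print.voxel_service <- function(x, ...) {
  jobs <- list.dirs(file.path(x$root, "jobs"), recursive = FALSE)
  cat(sprintf("<voxel_service> root %s, %d job(s)\n", x$root, length(jobs)))
  invisible(x)
}

job_dir <- function(svc, job_id) {
  d <- file.path(svc$root, "jobs", job_id)
  if (!dir.exists(d)) stop("not-found: unknown job ", job_id, call. = FALSE)
  d
}

read_job <- function(svc, job_id) {
  jsonlite::fromJSON(file.path(job_dir(svc, job_id), "job.json"))
}

write_job <- function(dir, job) {
  jsonlite::write_json(job, file.path(dir, "job.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
}

#' Create a job
#'
#' Initializes a job entry in status `created` and returns its ID.
#'
#' @param svc A [voxel_service()].
#' @return Job ID (character token).
#' @export
svc_create_job <- function(svc) {
  job_id <- paste0("job-", format(Sys.time(), "%Y%m%d%H%M%S"), "-",
                   paste(sample(c(letters, 0:9), 10, replace = TRUE),
                         collapse = ""))
  d <- file.path(svc$root, "jobs", job_id)
  dir.create(file.path(d, "input"), recursive = TRUE)
  dir.create(file.path(d, "output"))
  write_job(d, list(job_id = job_id, status = "created",
                    learning_type = NULL,
                    created_at = as.character(Sys.time()),
                    error_message = NULL))
  jsonlite::write_json(list(), file.path(d, "files.json"))
  job_id
}

read_files <- function(d) {
  f <- jsonlite::fromJSON(file.path(d, "files.json"), simplifyDataFrame = TRUE)
  if (length(f) == 0L)
    return(data.frame(file_id = character(), role = character(),
                      filename = character(), size = numeric()))
  f
}

write_files <- function(d, files) {
  jsonlite::write_json(files, file.path(d, "files.json"), digits = I(17))
}

#' Upload an input file to a job
#'
#' Bytes are stored verbatim and registered with role `input`. Only jobs
#' still in status `created` accept uploads.
#'
#' @param svc A [voxel_service()].
#' @param job_id Job ID from [svc_create_job()].
#' @param bytes Raw vector, or a path to a file to upload.
#' @param filename Name recorded for the file.
#' @return File ID (character token).
#' @export
svc_upload_file <- function(svc, job_id, bytes, filename) {
  d <- job_dir(svc, job_id)
  job <- read_job(svc, job_id)
  if (job$status != "created")
    stop("state error: job ", job_id, " is '", job$status,
         "', uploads are only accepted before launch", call. = FALSE)
  if (is.character(bytes) && length(bytes) == 1L && file.exists(bytes))
    bytes <- readBin(bytes, "raw", file.info(bytes)$size)
  stopifnot(is.raw(bytes))
  files <- read_files(d)
  file_id <- sprintf("file-%03d", nrow(files) + 1L)
  writeBin(bytes, file.path(d, "input", paste0(file_id, "_", filename)))
  files <- rbind(files, data.frame(file_id = file_id, role = "input",
                                   filename = filename,
                                   size = length(bytes)))
  write_files(d, files)
  file_id
}

#' Launch a learning run on a job
#'
#' Validates that the required inputs are present, marks the job
#' `running`, and executes the learning script. On success the outputs
#' are registered and the status becomes `done`; on failure it becomes
#' `error` with a message.
#'
#' Learning types: `"train"` (inputs: a `request.json` with fields
#' `model`, `seed` and optional `hyperparameters`; a `features.json`
#' holding the training table) and `"infer"` (inputs: a model archive
#' `model.vxl` and a volume file; `request.json` may carry `block_shape`).
#'
#' @param svc A [voxel_service()].
#' @param job_id Job ID.
#' @param learning_type `"train"` or `"infer"`.
#' @param wait If `TRUE`, block until the job leaves `running`. With
#'   `wait = FALSE` (the default) the worker runs asynchronously in a
#'   separate R process and [svc_get_status()] is polled.
#' @return `job_id`, invisibly.
#' @export
svc_launch_learning <- function(svc, job_id, learning_type = c("train", "infer"),
                                wait = FALSE) {
  learning_type <- match.arg(learning_type)
  d <- job_dir(svc, job_id)
  job <- read_job(svc, job_id)
  if (job$status != "created")
    stop("state error: job already launched", call. = FALSE)
  files <- read_files(d)
  if (nrow(files) == 0L)
    stop("validation error: no input files uploaded", call. = FALSE)
  need <- if (learning_type == "train") c("request.json", "features.json")
          else c("request.json", "model.vxl")
  missing <- setdiff(need, files$filename)
  if (length(missing))
    stop("validation error: missing required input(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  job$status <- "running"
  job$learning_type <- learning_type
  write_job(d, job)
  worker <- system.file("worker", "run_job.R", package = "voxelearn")
  rscript <- file.path(R.home("bin"), "Rscript")
  if (wait) {
    system2(rscript, c(worker, shQuote(d)), stdout = FALSE, stderr = FALSE)
  } else {
    system2(rscript, c(worker, shQuote(d)), stdout = FALSE, stderr = FALSE,
            wait = FALSE)
  }
  invisible(job_id)
}

#' Poll a job's status
#'
#' @param svc A [voxel_service()].
#' @param job_id Job ID.
#' @return One of `"created"`, `"running"`, `"done"`, `"error"`.
#' @export
svc_get_status <- function(svc, job_id) {
  read_job(svc, job_id)$status
}

#' Wait until a job completes
#'
#' Polls [svc_get_status()] until the job reaches `done` or `error`.
#'
#' @param svc A [voxel_service()].
#' @param job_id Job ID.
#' @param timeout Seconds to wait before giving up.
#' @param interval Polling interval in seconds.
#' @return Final status.
#' @export
svc_await <- function(svc, job_id, timeout = 120, interval = 0.2) {
  t0 <- Sys.time()
  repeat {
    st <- svc_get_status(svc, job_id)
    if (st %in% c("done", "error")) return(st)
    if (as.numeric(Sys.time() - t0, units = "secs") > timeout)
      stop("timed out waiting for job ", job_id, " (status ", st, ")",
           call. = FALSE)
    Sys.sleep(interval)
  }
}

#' List a job's files / download one file
#'
#' @param svc A [voxel_service()].
#' @param job_id Job ID.
#' @param file_id File ID from [svc_upload_file()] or [svc_list_files()].
#' @return `svc_list_files`: tibble of file records (`file_id`, `role`,
#'   `filename`, `size`). `svc_get_file`: raw vector of the file bytes.
#' @export
svc_list_files <- function(svc, job_id) {
  d <- job_dir(svc, job_id)
  tibble::as_tibble(read_files(d))
}

#' @rdname svc_list_files
#' @export
svc_get_file <- function(svc, job_id, file_id) {
  d <- job_dir(svc, job_id)
  files <- read_files(d)
  row <- files[files$file_id == file_id, ]
  if (nrow(row) == 0L)
    stop("not-found: no file ", file_id, " in job ", job_id, call. = FALSE)
  sub <- if (row$role == "input") "input" else "output"
  path <- file.path(d, sub, paste0(file_id, "_", row$filename))
  readBin(path, "raw", file.info(path)$size)
}

#' Job error message (if any)
#'
#' @param svc A [voxel_service()].
#' @param job_id Job ID.
#' @return The message string, or `NULL`.
#' @export
svc_error_message <- function(svc, job_id) {
  job <- read_job(svc, job_id)
  job$error_message
}

#' Dispatch a REST-style request to the service
#'
#' Maps the six HTTP endpoints of the remote-learning API onto the
#' service operations:
#'
#' * `POST /jobs` — create a job, returns `{"job_id": ...}`
#' * `POST /jobs/{jobid}/file` — upload (body: raw bytes; `filename`
#'   passed separately), returns `{"file_id": ...}`
#' * `PUT /learning/{jobid}` — launch (body: `{"type": "train"|"infer"}`)
#' * `GET /jobs/{jobid}/status` — returns `{"status": ...}`
#' * `GET /jobs/{jobid}/files` — returns the file list
#' * `GET /jobs/{jobid}/files/{fileid}` — returns the file bytes
#'
#' Responses are lists with `status_code` (200, 400, 404 or 409) and
#' `body`.
#'
#' @param svc A [voxel_service()].
#' @param method HTTP method string.
#' @param path Endpoint path.
#' @param body Request body (list, or raw vector for uploads).
#' @param filename Filename for uploads.
#' @return List with `status_code` and `body`.
#' @export
svc_handle_request <- function(svc, method, path, body = NULL,
                               filename = NULL) {
  parts <- strsplit(sub("^/", "", path), "/")[[1]]
  respond <- function(code, body) list(status_code = code, body = body)
  catch <- function(expr) {
    tryCatch(expr, error = function(e) {
      msg <- conditionMessage(e)
      code <- if (grepl("^not-found", msg)) 404L
              else if (grepl("^state error", msg)) 409L else 400L
      respond(code, list(error = msg))
    })
  }
  if (method == "POST" && identical(parts, "jobs"))
    return(catch(respond(200L, list(job_id = svc_create_job(svc)))))
  if (method == "POST" && length(parts) == 3L && parts[1] == "jobs" &&
      parts[3] == "file")
    return(catch(respond(200L, list(
      file_id = svc_upload_file(svc, parts[2], body,
                                filename %||% "upload.bin")))))
  if (method == "PUT" && length(parts) == 2L && parts[1] == "learning")
    return(catch({
      svc_launch_learning(svc, parts[2], body$type)
      respond(200L, list(job_id = parts[2], status = "running"))
    }))
  if (method == "GET" && length(parts) == 3L && parts[1] == "jobs" &&
      parts[3] == "status")
    return(catch(respond(200L, list(status = svc_get_status(svc, parts[2])))))
  if (method == "GET" && length(parts) == 3L && parts[1] == "jobs" &&
      parts[3] == "files")
    return(catch(respond(200L, svc_list_files(svc, parts[2]))))
  if (method == "GET" && length(parts) == 4L && parts[1] == "jobs" &&
      parts[3] == "files")
    return(catch(respond(200L, svc_get_file(svc, parts[2], parts[4]))))
  respond(404L, list(error = paste("no such endpoint:", method, path)))
}

# ---- payload helpers ----------------------------------------------------

#' Serialize / read a training table as JSON
#'
#' The transport dialect for remote training: feature names, per-voxel
#' feature rows, labels and voxel IDs.
#'
#' @param x Feature matrix (rows = tagged voxels).
#' @param y Binary labels.
#' @param voxel_id Optional voxel IDs.
#' @param path File path.
#' @return `read_training_json` returns a list with `x` (matrix with
#'   `spec_hash` attribute), `y` and `voxel_id`.
#' @export
write_training_json <- function(x, y, path, voxel_id = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  obj <- list(feature_names = colnames(x),
              spec_hash = attr(x, "spec_hash"),
              rows = unname(apply(x, 1, as.numeric, simplify = FALSE)),
              labels = as.integer(y),
              voxel_id = voxel_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname write_training_json
#' @export
read_training_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  x <- if (is.matrix(obj$rows)) obj$rows
       else do.call(rbind, lapply(obj$rows, as.numeric))
  colnames(x) <- obj$feature_names
  attr(x, "spec_hash") <- obj$spec_hash
  list(x = x, y = as.integer(obj$labels), voxel_id = obj$voxel_id)
}

#' Run a training job through the service
#'
#' Convenience client that scripts the six-step workflow: create the job,
#' upload the training table and request, launch, poll to completion,
#' and download the trained model.
#'
#' @param svc A [voxel_service()].
#' @param x,y Training table (as for [train_classifier()]).
#' @param model `"rfc"`, `"mlp"`, `"xgb"`, `"svm"`, `"nbc"` or
#'   `"strong"`.
#' @param seed Training seed.
#' @param timeout Seconds to wait for completion.
#' @return The trained model, downloaded from the job's outputs.
#' @export
svc_train_remote <- function(svc, x, y, model = "rfc", seed = 0L,
                             timeout = 300) {
  job_id <- svc_create_job(svc)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  write_training_json(x, y, tmp)
  svc_upload_file(svc, job_id, tmp, "features.json")
  req <- tempfile(fileext = ".json")
  on.exit(unlink(req), add = TRUE)
  jsonlite::write_json(list(model = model, seed = seed), req,
                       auto_unbox = TRUE)
  svc_upload_file(svc, job_id, req, "request.json")
  svc_launch_learning(svc, job_id, "train")
  st <- svc_await(svc, job_id, timeout = timeout)
  if (st == "error")
    stop("remote training failed: ", svc_error_message(svc, job_id),
         call. = FALSE)
  files <- svc_list_files(svc, job_id)
  out <- files[files$role == "output" & files$filename == "model.vxl", ]
  bytes <- svc_get_file(svc, job_id, out$file_id[1])
  mf <- tempfile(fileext = ".vxl")
  on.exit(unlink(mf), add = TRUE)
  writeBin(bytes, mf)
  load_model(mf)
}
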