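tiny_table <- function(seed = 0) {
  d <- separable_clusters(15, 4, seed = seed)
  colnames(d$x) <- paste0("F", 1:4)
  d
}

test_that("jobs are created with distinct ids, empty files, status created", {
  svc <- voxel_service(withr::local_tempdir())
  j1 <- svc_create_job(svc)
  j2 <- svc_create_job(svc)
  expect_false(identical(j1, j2))
  expect_identical(svc_get_status(svc, j1), "created")
  expect_equal(nrow(svc_list_files(svc, j1)), 0L)
  expect_error(svc_get_status(svc, "job-unknown"), "not-found")
})

test_that("uploads round-trip verbatim and respect the job state", {
  svc <- voxel_service(withr::local_tempdir())
  j <- svc_create_job(svc)
  payload <- as.raw(sample(0:255, 1000, replace = TRUE))
  fid <- svc_upload_file(svc, j, payload, "blob.bin")
  expect_identical(svc_get_file(svc, j, fid), payload)
  expect_error(svc_upload_file(svc, "nope", payload, "x"), "not-found")
  expect_error(svc_get_file(svc, j, "file-999"), "not-found")
})

test_that("launch validates inputs before running", {
  svc <- voxel_service(withr::local_tempdir())
  j <- svc_create_job(svc)
  expect_error(svc_launch_learning(svc, j, "train"), "no input files")
  svc_upload_file(svc, j, charToRaw("{}"), "request.json")
  expect_error(svc_launch_learning(svc, j, "train"), "features.json")
  expect_identical(svc_get_status(svc, j), "created")
})

test_that("a corrupt input yields a terminal error status with a message", {
  svc <- voxel_service(withr::local_tempdir())
  j <- svc_create_job(svc)
  svc_upload_file(svc, j, charToRaw('{"model":"rfc","seed":0}'), "request.json")
  svc_upload_file(svc, j, charToRaw("{this is not json"), "features.json")
  svc_launch_learning(svc, j, "train", wait = TRUE)
  expect_identical(svc_get_status(svc, j), "error")
  expect_gt(nchar(svc_error_message(svc, j)), 0)
  # a launched job accepts no more uploads
  expect_error(svc_upload_file(svc, j, raw(1), "late.bin"), "state error")
})

test_that("the six-step workflow trains remotely and reproduces local results", {
  svc <- voxel_service(withr::local_tempdir())
  d <- tiny_table()
  # step 1: create
  j <- svc_handle_request(svc, "POST", "/jobs")$body$job_id
  # step 2: upload inputs
  ft <- withr::local_tempfile(fileext = ".json")
  write_training_json(d$x, d$y, ft)
  svc_handle_request(svc, "POST", paste0("/jobs/", j, "/file"),
                     body = readBin(ft, "raw", file.info(ft)$size),
                     filename = "features.json")
  svc_handle_request(svc, "POST", paste0("/jobs/", j, "/file"),
                     body = charToRaw('{"model":"rfc","seed":5}'),
                     filename = "request.json")
  # step 3: launch (asynchronous worker)
  r <- svc_handle_request(svc, "PUT", paste0("/learning/", j),
                          body = list(type = "train"))
  expect_equal(r$status_code, 200L)
  # step 4: poll
  st <- svc_await(svc, j, timeout = 120)
  expect_identical(st, "done")
  # step 5: list outputs
  files <- svc_handle_request(svc, "GET", paste0("/jobs/", j, "/files"))$body
  out <- files[files$role == "output", ]
  expect_gte(nrow(out), 1L)
  expect_true("model.vxl" %in% out$filename)
  # step 6: download and compare against a local train with the same seed
  bytes <- svc_handle_request(
    svc, "GET", paste0("/jobs/", j, "/files/", out$file_id[1]))$body
  mf <- withr::local_tempfile(fileext = ".vxl")
  writeBin(bytes, mf)
  remote <- load_model(mf)
  local <- train_classifier(classifier_spec("rfc", seed = 5), d$x, d$y)
  expect_lt(max(abs(predict_proba(remote, d$x) - predict_proba(local, d$x))),
            1e-6)
  # unknown endpoints and ids surface as 404s
  expect_equal(svc_handle_request(svc, "GET", "/jobs/zzz/status")$status_code,
               404L)
  expect_equal(svc_handle_request(svc, "GET", "/nope")$status_code, 404L)
})

test_that("concurrent jobs keep their state isolated", {
  svc <- voxel_service(withr::local_tempdir())
  seeds <- 1:4
  jobs <- character(4)
  tables <- lapply(seeds, function(s) tiny_table(seed = s))
  for (i in seq_along(seeds)) {
    j <- svc_create_job(svc)
    ft <- tempfile(fileext = ".json")
    write_training_json(tables[[i]]$x, tables[[i]]$y, ft)
    svc_upload_file(svc, j, ft, "features.json")
    unlink(ft)
    svc_upload_file(svc, j,
                    charToRaw(sprintf('{"model":"rfc","seed":%d}', seeds[i])),
                    "request.json")
    jobs[i] <- j
  }
  for (j in jobs) svc_launch_learning(svc, j, "train")  # all in flight
  for (j in jobs) expect_identical(svc_await(svc, j, timeout = 180), "done")
  for (i in seq_along(jobs)) {
    files <- svc_list_files(svc, jobs[i])
    out <- files[files$role == "output" & files$filename == "model.vxl", ]
    mf <- tempfile(fileext = ".vxl")
    writeBin(svc_get_file(svc, jobs[i], out$file_id[1]), mf)
    remote <- load_model(mf)
    unlink(mf)
    local <- train_classifier(classifier_spec("rfc", seed = seeds[i]),
                              tables[[i]]$x, tables[[i]]$y)
    expect_identical(predict_proba(remote, tables[[i]]$x),
                     predict_proba(local, tables[[i]]$x))
  }
})
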