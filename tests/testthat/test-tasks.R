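test_that("the registry exposes six tasks and nine error classes", {
  tasks <- lapply(1:6, load_task)
  expect_length(tasks, 6L)
  expect_error(load_task(7), "1..6")

  ec <- error_classes()
  expect_equal(nrow(ec), 9L)
  expect_setequal(sort(unique(unlist(ec$applicable_tasks))), 1:6)
})

test_that("per-task error applicability matches the published rules", {
  ec <- error_classes()
  app <- stats::setNames(ec$applicable_tasks, ec$class)
  expect_equal(app[["OFF_TIP_CONTACT"]], 1:6)
  expect_equal(app[["WORKSPACE_BOUNDARY"]], 1:6)
  expect_equal(app[["TARGET_CONTACT_EXCESS"]], c(1L, 2L))
  expect_equal(app[["CONTAINER_CONTACT"]], c(1L, 2L))
  expect_equal(app[["INSTRUMENT_CLASH"]], c(3L, 4L))
  expect_equal(app[["OVAL_CONTACT_EXCESS"]], 4L)
  expect_equal(app[["OFF_PATH_TIME"]], c(1L, 2L, 4L, 6L))
  expect_equal(app[["DIATHERMY_OFF_TARGET"]], c(5L, 6L))
  expect_equal(app[["EXCESS_BURN_TIME"]], c(5L, 6L))

  expect_false("INSTRUMENT_CLASH" %in% load_task(1)$error_classes)
  t5 <- load_task(5)
  expect_true(all(c("DIATHERMY_OFF_TARGET", "EXCESS_BURN_TIME") %in% t5$error_classes))
})

test_that("task 3 is bimanual with no dominant-hand option", {
  t3 <- load_task(3)
  expect_true(t3$bimanual)
  expect_false(t3$dominant_hand_configurable)
  expect_true(all(vapply(c(1, 2, 4, 5, 6),
                         function(i) load_task(i)$dominant_hand_configurable,
                         logical(1))))
})

test_that("completion criterion kind matches the task", {
  kinds <- vapply(1:6, function(i) load_task(i)$completion$kind, character(1))
  expect_equal(kinds, c("PLACED_IN_SHAPE", "TRANSFER_THEN_PLACED",
                        "TRAVERSAL_COMPLETE", "REMOVE_REINSERT_COUNT",
                        "ALL_TARGETS_CAUTERIZED", "PLACED_AND_CAUTERIZED"))
})

test_that("default weights honour the published constraints", {
  w <- default_weights()
  expect_equal(unname(w[["DIATHERMY_OFF_TARGET"]]), 5L)
  expect_true(all(w >= 1 & w <= 5))
  expect_setequal(names(w), error_classes()$class)

  w2 <- default_weights(c(WORKSPACE_BOUNDARY = 3))
  expect_equal(unname(w2[["WORKSPACE_BOUNDARY"]]), 3L)
  expect_equal(w2[names(w2) != "WORKSPACE_BOUNDARY"],
               w[names(w) != "WORKSPACE_BOUNDARY"])
})

test_that("weight validation flags range and coverage violations", {
  expect_length(validate_weights(default_weights()), 0L)
  bad <- default_weights(); bad[["INSTRUMENT_CLASH"]] <- 6L
  expect_match(validate_weights(bad), "INSTRUMENT_CLASH")
  incomplete <- default_weights()[-9L]
  expect_match(validate_weights(incomplete), "missing class")
})

test_that("task definitions round-trip through scene JSON", {
  for (tid in c(1L, 3L, 5L)) {
    task <- load_task(tid)
    f <- tempfile(fileext = ".json")
    write_task_json(task, f)
    back <- load_task(tid, scene_file = f)
    expect_equal(names(back$shapes), names(task$shapes))
    for (nm in names(task$shapes))
      expect_equal(back$shapes[[nm]], task$shapes[[nm]], tolerance = 1e-12)
    for (h in c("left", "right"))
      expect_equal(unclass(back$ideal_path[[h]]), unclass(task$ideal_path[[h]]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(back$completion$kind, task$completion$kind)
    expect_equal(back$pivots, task$pivots)
  }
})

test_that("scene JSON overrides replace named pieces and reject mismatches", {
  task <- load_task(1)
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    task_id = 1, shapes = list(list(name = "target", kind = "sphere",
                                    center = c(0, 150, 0), radius = 10))),
    f, auto_unbox = TRUE)
  over <- load_task(1, scene_file = f)
  expect_equal(over$shapes$target$radius, 10)
  expect_equal(over$shapes$goal, task$shapes$goal)

  jsonlite::write_json(list(task_id = 2), f, auto_unbox = TRUE)
  expect_error(load_task(1, scene_file = f), "does not match")

  jsonlite::write_json(list(shapes = list(list(kind = "sphere"))), f,
                       auto_unbox = TRUE)
  expect_error(load_task(1, scene_file = f), "no name")
})
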