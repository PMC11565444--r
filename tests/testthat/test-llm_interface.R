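test_that("extractor prompts carry all five components for every field and variant", {
  for (f in list_fields()) {
    for (v in 1:2) {
      p <- build_extractor_prompt(f, v, "Report body.")
      expect_s3_class(p, "prompt_spec")
      expect_setequal(names(p$sections),
                      c("role", "task", "format_constraints", "examples",
                        "uncertainty_handling"))
      expect_true(all(nzchar(unlist(p$sections))))
      expect_match(p$rendered, "Not Available", fixed = TRUE)
      expect_match(p$rendered, get_field_schema(f)$query_key, fixed = TRUE)
    }
  }
  expect_error(build_extractor_prompt("histologic_grade", 3, "x"))
  expect_error(build_extractor_prompt("histologic_grade", 1, "  "), "non-empty")
})

test_that("local invasion prompt teaches the worked example and the T4A alias", {
  for (v in 1:2) {
    p <- build_extractor_prompt("local_invasion", v, "some report")
    expect_match(p$rendered, "Tumour invades muscularis propria", fixed = TRUE)
    expect_match(p$rendered, "pT2", fixed = TRUE)
    expect_match(p$rendered, "T4A", fixed = TRUE)
  }
})

test_that("prompt rendering is deterministic and variants differ in form only", {
  a <- build_extractor_prompt("tumour_site", 1, "text one")
  b <- build_extractor_prompt("tumour_site", 1, "text one")
  expect_identical(a$rendered, b$rendered)
  v2 <- build_extractor_prompt("tumour_site", 2, "text one")
  expect_false(identical(a$rendered, v2$rendered))
  # same semantic payload: both enumerate the same categories
  for (val in setdiff(get_field_schema("tumour_site")$values, "NA")) {
    expect_match(a$rendered, val, fixed = TRUE)
    expect_match(v2$rendered, val, fixed = TRUE)
  }
})

test_that("validator prompt embeds the value and the three output labels", {
  p <- build_validator_prompt("histologic_grade", "a report", "High")
  expect_match(p$rendered, "\"High\"", fixed = TRUE)
  for (k in c("Correctness", "Confidence", "Corrected")) {
    expect_match(p$rendered, k, fixed = TRUE)
  }
  expect_error(build_validator_prompt("histologic_grade", "a report", ""),
               "canonical")
  expect_error(build_validator_prompt("histologic_grade", "a report", "banana"),
               "canonical")
  # NA sentinel is a legal extractor value
  expect_s3_class(build_validator_prompt("local_invasion", "a report", "pTX"),
                  "prompt_spec")
})

test_that("extraction replies round-trip every canonical value", {
  for (f in list_fields()) {
    qk <- get_field_schema(f)$query_key
    vals <- canonical_values(f)
    if (length(vals) > 30) vals <- c(vals[1:20], vals[length(vals)])
    for (v in vals) {
      r <- parse_extraction_reply(sprintf('{"%s": "%s"}', qk, v), f)
      expect_true(r$parse_ok, label = paste(f, v))
      expect_identical(r$value, v)
    }
  }
})

test_that("extraction reply parsing tolerates fences, prose and short keys", {
  r <- parse_extraction_reply('```json\n{"Grade":"high"}\n```', "histologic_grade")
  expect_true(r$parse_ok)
  expect_identical(r$value, "High")
  r <- parse_extraction_reply('Sure! Here it is: {"Local Invasion": "T4A"} Hope that helps.',
                              "local_invasion")
  expect_identical(r$value, "pT4a")
  # first JSON object wins
  r <- parse_extraction_reply('{"Local Invasion": "pT2"} {"Local Invasion": "pT3"}',
                              "local_invasion")
  expect_identical(r$value, "pT2")
  expect_false(parse_extraction_reply("I cannot determine this.", "histologic_grade")$parse_ok)
  expect_false(parse_extraction_reply('{"Wrong Key": "High"}', "histologic_grade")$parse_ok)
  expect_false(parse_extraction_reply('{"Grade": "banana"}', "histologic_grade")$parse_ok)
})

test_that("validator replies are validated strictly", {
  r <- parse_validator_reply('{"Correctness":"Correct","Confidence":90,"Corrected":"pT3"}')
  expect_true(r$parse_ok)
  expect_identical(r$payload$correctness, "correct")
  expect_identical(r$payload$confidence, 90L)
  expect_identical(r$payload$corrected, "pT3")
  # keys case-insensitive
  expect_true(parse_validator_reply('{"correctness":"incorrect","confidence":5,"corrected":"NA"}')$parse_ok)
  expect_false(parse_validator_reply('{"Correctness":"Correct","Confidence":150,"Corrected":"pT3"}')$parse_ok)
  expect_false(parse_validator_reply('{"Correctness":"Correct","Confidence":90}')$parse_ok)
  expect_false(parse_validator_reply('{"Correctness":"maybe","Confidence":50,"Corrected":"pT3"}')$parse_ok)
  expect_false(parse_validator_reply('not json at all')$parse_ok)
})

test_that("the backend contract holds: exact counts and seeded reproducibility", {
  case <- generate_case(11)
  be <- simulated_backend(responder_profile(), list(case))
  prompt <- build_extractor_prompt("histologic_grade", 1, case$report_text,
                                   report_id = case$report_id)$rendered
  out1 <- backend_sample(be, prompt, 7L, seed = 99L)
  out2 <- backend_sample(be, prompt, 7L, seed = 99L)
  expect_length(out1, 7L)
  expect_identical(out1, out2)
  out3 <- backend_sample(be, prompt, 7L, seed = 100L)
  expect_false(identical(out1, out3))
  # production prompts carry no marker; the simulated backend refuses them
  bare <- build_extractor_prompt("histologic_grade", 1, case$report_text)$rendered
  expect_error(backend_sample(be, bare, 5L, 1L), "case marker")
  # a live backend without a transport is configuration, not magic
  expect_error(backend_sample(live_backend(), "prompt", 2L, 1L), "request_fn")
})
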