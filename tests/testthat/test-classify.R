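test_that("classifier reproduces the canonical type definitions", {
  # harmonic stack, fundamental below 5 kHz -> low-frequency harmonic
  lfh <- syllable_record("a", 0, 60, "4/4/4/4/32", purity = "harmonic",
                         fundamental = 4)
  expect_identical(classify_syllable(lfh)$syll_type, "lfh")

  # duration of 4 ms with a flat track -> short
  expect_identical(
    classify_syllable(syllable_record("b", 0, 4, "90/91/90/89/92"))$syll_type,
    "short")

  # rise 20 / fall 18 with one reversal -> chevron
  chev <- syllable_record("c", 0, 30, "70/90/72/69/91", reversals = 1)
  expect_identical(classify_syllable(chev)$syll_type, "chevron")

  # two elements, centers 95 then 65 (step -30) -> 1 freq. step
  ofs <- classify_syllable(
    syllable_record("d", 0, 40, "94/95/95/93/96;66/65/65/64/67"))
  expect_identical(ofs$syll_type, "one_freq_step")
  expect_equal(ofs$step_sizes, -30, ignore_attr = TRUE)

  # modulation of 4 kHz over 19 ms -> flat
  expect_identical(
    classify_syllable(syllable_record("e", 0, 19, "70/72/74/70/74"))$syll_type,
    "flat")

  # three elements, centers 98 / 67 / 99 -> 2 freq. step, steps -31 / +32
  tfs <- classify_syllable(syllable_record(
    "f", 0, 60, "98/98/98/97/99;67/67/67/66/68;99/99/99/98/100"))
  expect_identical(tfs$syll_type, "two_freq_step")
  expect_equal(tfs$step_sizes, c(-31, 32), ignore_attr = TRUE)

  # two or more reversals -> complex
  cx <- syllable_record("g", 0, 40, "80/88/82/79/89", reversals = 2)
  expect_identical(classify_syllable(cx)$syll_type, "complex")

  # broadband warble flag -> noisy
  nz <- syllable_record("h", 0, 50, "60/70/55/10/120", is_noisy_broadband = TRUE)
  expect_identical(classify_syllable(nz)$syll_type, "noisy")

  # net modulation of at least 6 kHz -> up/down FM
  expect_identical(
    classify_syllable(syllable_record("i", 0, 30, "70/75/80/69/81"))$syll_type,
    "up_fm")
  expect_identical(
    classify_syllable(syllable_record("j", 0, 30, "80/75/70/69/81"))$syll_type,
    "down_fm")

  # U-shape: trough at least 6 kHz under both endpoints -> reverse chevron
  expect_identical(
    classify_syllable(syllable_record("k", 0, 30, "90/80/89/79/91",
                                      reversals = 1))$syll_type,
    "reverse_chevron")
})

test_that("threshold boundaries are inclusive exactly as specified", {
  # duration exactly 5 ms is short
  expect_identical(
    classify_syllable(syllable_record("a", 0, 5, "90/90/90/89/91"))$syll_type,
    "short")
  # modulation of exactly 6 kHz satisfies the FM rule (not flat)
  expect_identical(
    classify_syllable(syllable_record("b", 0, 20, "70/73/76/70/76"))$syll_type,
    "up_fm")
  # modulation just under 6 kHz stays flat
  expect_identical(
    classify_syllable(syllable_record("c", 0, 20, "70/73/75.9/70/75.9"))$syll_type,
    "flat")
  # a step of exactly 10 kHz qualifies as a frequency step
  expect_identical(
    classify_syllable(
      syllable_record("d", 0, 30, "90/90/90/89/91;80/80/80/79/81"))$syll_type,
    "one_freq_step")
  # a 9.9 kHz two-element step falls through to the shape rules
  expect_identical(
    classify_syllable(
      syllable_record("e", 0, 30, "90/90/90/89/91;80.2/80.1/80.3/79/81"))$syll_type,
    "down_fm")
  # chevron boundary: peak exactly 6 kHz above both endpoints
  expect_identical(
    classify_syllable(syllable_record("f", 0, 30, "80/86/80/79/87",
                                      reversals = 1))$syll_type,
    "chevron")
})

test_that("precedence: structural rules fire before shape rules", {
  # short beats stepped when a syllable is both
  both <- syllable_record("a", 0, 4.5, "95/95/95/94/96;65/65/65/64/66")
  expect_identical(classify_syllable(both)$syll_type, "short")
  # lfh beats everything
  expect_identical(
    classify_syllable(syllable_record("b", 0, 4, "3/3/3/3/24", fundamental = 3,
                                      purity = "harmonic"))$syll_type,
    "lfh")
  # step rule beats reversal count
  expect_identical(
    classify_syllable(syllable_record("c", 0, 30,
                                      "95/95/95/94/96;65/65/65/64/66",
                                      reversals = 2))$syll_type,
    "one_freq_step")
})

test_that("classification is a total, deterministic, time-invariant partition", {
  set.seed(101)
  for (i in 1:300) {
    rec <- random_record(sprintf("r%03d", i))
    c1 <- classify_syllable(rec)
    expect_true(c1$syll_type %in% syllable_types())
    expect_identical(classify_syllable(rec)$syll_type, c1$syll_type)
    # uniform time translation leaves the classification unchanged
    shifted <- rec
    shifted$onset <- rec$onset + 5000
    shifted$offset <- rec$offset + 5000
    expect_identical(classify_syllable(shifted)$syll_type, c1$syll_type)
    # step_sizes length is elements - 1
    expect_length(c1$step_sizes, nrow(rec$elements) - 1L)
  }
})

test_that("classify_table preserves order, aggregates errors, handles empty input", {
  empty <- classify_table(ann_row("x", 0, 1, "50/50/50/49/51")[0, ])
  expect_identical(nrow(empty), 0L)

  tbl <- rbind(ann_row("a", 0, 19, "70/72/74/70/74"),
               ann_row("b", 100, 104, "90/91/90/89/92"),
               ann_row("c", 300, 330, "70/90/72/69/91", reversals = 1))
  out <- classify_table(tbl)
  expect_identical(out$syll_type, c("flat", "short", "chevron"))
  expect_identical(out$id, tbl$id)
  expect_s3_class(attr(out, "type_counts"), "table")

  bad <- rbind(tbl,
               ann_row("d", 10, 5, "70/72/74/70/74"),          # offset < onset
               ann_row("e", 0, 10, "70/72/74/70/74;1/1/1/1/1;2/2/2/2/2;3/3/3/3/3"))
  err <- tryCatch(classify_table(bad), usvrep_malformed = function(e) conditionMessage(e))
  expect_match(err, "row 4")
  expect_match(err, "row 5")
})

test_that("non-positive frequencies and >3 elements are rejected", {
  expect_error(syllable_record("a", 0, 10, "0/5/5/0/6"), class = "usvrep_malformed")
  expect_error(
    syllable_record("b", 0, 10,
                    "9/9/9/8/10;9/9/9/8/10;9/9/9/8/10;9/9/9/8/10"),
    class = "usvrep_malformed")
})

test_that("annotation IO round-trips classified tables", {
  tbl <- rbind(ann_row("a", 0, 19, "70/72/74/70/74"),
               ann_row("b", 100, 104, "90/91/90/89/92", fundamental = 4,
                       purity = "harmonic"))
  out <- classify_table(tbl)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(out, path)
  back <- read_annotations(path)
  expect_identical(back$syll_type, out$syll_type)
  expect_identical(back$elements, out$elements)
  expect_equal(back$fundamental_khz, out$fundamental_khz)
  reclassified <- classify_table(back)
  expect_identical(reclassified$syll_type, out$syll_type)
})
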