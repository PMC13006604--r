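# Channel selection: name canonicalization, lexicon matching, LLM prompt
# round trip, consensus Jaccard agreement.

test_that("channel names canonicalize per the stated stripping rules", {
  expect_equal(normalize_channel_name("CD31"), "cd31")
  expect_equal(normalize_channel_name("DNA1_Ir191"), "dna1")
  expect_equal(normalize_channel_name("aSMA (Pt196)"), "asma")
  expect_equal(normalize_channel_name("141Pr-Col1A1"), "col1a1")
  expect_equal(normalize_channel_name("αSMA"), "asma")
  expect_equal(normalize_channel_name("β-Catenin"), "bcatenin")
  # marker names that merely look like metal tags survive intact
  expect_equal(normalize_channel_name("CD103"), "cd103")
  expect_equal(normalize_channel_name("CD115"), "cd115")
  # idempotence
  nms <- c("CD31", "DNA1_Ir191", "aSMA (Pt196)", "Vimentin_Nd143")
  once <- normalize_channel_name(nms)
  expect_equal(normalize_channel_name(once), once)
  expect_error(normalize_channel_name(""), "non-empty")
})

test_that("lexicon assignment groups matching channels and ignores the rest", {
  asn <- assign_by_lexicon("DAPI", "h_and_e")
  expect_equal(asn$assignment$nuclei, "DAPI")
  expect_length(asn$unassigned, 0)

  asn <- assign_by_lexicon(c("DNA1_Ir191", "CD31", "Vimentin"), "h_and_e")
  expect_equal(asn$assignment$nuclei, "DNA1_Ir191")
  expect_equal(asn$assignment$epithelial, "Vimentin")
  expect_equal(asn$unassigned, "CD31")

  empty <- assign_by_lexicon(character(), "h_and_e")
  expect_true(all(lengths(empty$assignment) == 0))
  expect_length(empty$unassigned, 0)
})

test_that("lexicon assignment is order-independent and covers every channel", {
  chans <- c("DNA1_Ir191", "Col1A1_Tm169", "panCK_Eu153", "Ter119_Sm154",
             "CD31_Pt195", "Unknown1")
  a <- assign_by_lexicon(chans, "h_and_e")
  b <- assign_by_lexicon(rev(chans), "h_and_e")
  for (cls in names(a$assignment)) {
    expect_setequal(a$assignment[[cls]], b$assignment[[cls]])
  }
  covered <- union(unlist(a$assignment), a$unassigned)
  expect_setequal(covered, chans)
  # unassigned = channels matching no class
  expect_length(intersect(a$unassigned, unlist(a$assignment)), 0)
})

test_that("unknown stain errors listing available presets", {
  expect_error(assign_by_lexicon("DAPI", "nope"), "h_and_e")
})

test_that("prompt contains stain, classes, colors, every channel once, and schema", {
  prof <- stain_preset("h_and_e")
  chans <- c("DNA1_Ir191", "CD31", "Vimentin")
  p <- build_llm_prompt("h_and_e", prof, chans)
  expect_identical(p, build_llm_prompt("h_and_e", prof, chans))  # determinism
  for (ch in chans) {
    expect_equal(sum(grepl(paste0("^- ", ch, "$"),
                           strsplit(p, "\n")[[1]], fixed = FALSE)), 1)
  }
  for (cl in prof$classes) {
    expect_match(p, paste0('"', cl$name, '"'), fixed = TRUE)
    expect_match(p, cl$description, fixed = TRUE)
  }
  expect_match(p, "Stain: h_and_e", fixed = TRUE)
  expect_match(p, "JSON", fixed = TRUE)
  # schema enumerates exactly one key per class
  schema_line <- grep("exactly these keys", strsplit(p, "\n")[[1]], value = TRUE)
  expect_length(schema_line, 1)
})

test_that("response parsing restricts to known channels and round-trips", {
  prof <- stain_preset("h_and_e")
  chans <- c("DNA1_Ir191", "Vimentin", "CD31")
  asn <- assign_by_lexicon(chans, profile = prof)
  parsed <- parse_llm_response(as.character(format_llm_response(asn)),
                               prof, chans)
  for (cls in names(asn$assignment)) {
    expect_setequal(parsed$assignment[[cls]], asn$assignment[[cls]])
  }
  expect_setequal(parsed$unassigned, asn$unassigned)

  # unknown channel in the response is dropped with a warning
  resp <- '{"nuclei": ["DNA1_Ir191", "Ghost"], "eosinophilic": [],
            "epithelial": [], "erythrocytes": []}'
  expect_warning(out <- parse_llm_response(resp, prof, chans), "Ghost")
  expect_equal(out$assignment$nuclei, "DNA1_Ir191")

  # missing keys are empty, not errors
  out2 <- parse_llm_response('{"nuclei": ["DNA1_Ir191"]}', prof, chans)
  expect_length(out2$assignment$eosinophilic, 0)

  # garbage is a parse error carrying the raw text
  err <- tryCatch(parse_llm_response("total nonsense", prof, chans),
                  error = identity)
  expect_s3_class(err, "virtualstain_parse_error")
  expect_equal(err$raw_response, "total nonsense")
})

test_that("mock provider answers from the lexicon through the llm route", {
  chans <- c("DNA1_Ir191", "Vimentin", "CD31")
  via_llm <- select_channels(chans, "h_and_e", method = "llm")
  via_lex <- assign_by_lexicon(chans, "h_and_e")
  for (cls in names(via_lex$assignment)) {
    expect_setequal(via_llm$assignment[[cls]], via_lex$assignment[[cls]])
  }
})

test_that("consensus Jaccard reproduces hand-enumerated values", {
  mk <- function(...) channel_assignment(list(k = c(...)))
  # all identical -> 1
  res <- consensus_jaccard(list(mk("A", "B"), mk("A", "B"), mk("A", "B")))
  expect_equal(res$mean, 1)
  # {A,B},{A,B},{A,C}: consensus {A,B}; scores 1, 1, 1/3; mean 7/9
  res <- consensus_jaccard(list(mk("A", "B"), mk("A", "B"), mk("A", "C")))
  expect_equal(res$per_model, c(1, 1, 1 / 3))
  expect_equal(res$mean, 7 / 9)
  expect_setequal(res$consensus$assignment$k, c("A", "B"))
  # two disjoint singletons: no majority, consensus empty, mean 0
  res <- consensus_jaccard(list(mk("A"), mk("B")))
  expect_length(res$consensus$assignment$k, 0)
  expect_equal(res$mean, 0)
  # empty-vs-empty agreement counts as 1
  res <- consensus_jaccard(list(channel_assignment(list(k = character())),
                                channel_assignment(list(k = character()))))
  expect_equal(res$mean, 1)
})

test_that("consensus Jaccard is invariant to model order and bounded", {
  mk <- function(...) channel_assignment(list(k = c(...)))
  models <- list(mk("A", "B"), mk("B", "C"), mk("A", "C", "D"))
  base <- consensus_jaccard(models)
  for (i in 1:5) {
    set.seed(i)
    perm <- sample(3)
    res <- consensus_jaccard(models[perm])
    expect_equal(sort(res$per_model), sort(base$per_model))
    expect_equal(res$mean, base$mean)
    expect_true(all(res$per_model >= 0 & res$per_model <= 1))
  }
  expect_error(consensus_jaccard(list(mk("A"),
                                      channel_assignment(list(z = "A")))),
               "class sets")
})

test_that("tidy() turns an assignment into a class/channel tibble", {
  asn <- assign_by_lexicon(c("DNA1_Ir191", "CD31"), "h_and_e")
  tb <- tidy(asn)
  expect_s3_class(tb, "tbl_df")
  expect_true(all(c("class", "channel") %in% names(tb)))
  expect_true("(unassigned)" %in% tb$class)
})
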