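test_that("tokenizer splits the worked-example SMILES into 23 atoms", {
  toks <- tokenize_smiles("O=C(O)C(Oc1ccc(cc1C)Cl)C")
  expect_length(toks, 23L)
  expect_equal(sum(toks == "("), 6L)  # three '(' + three ')' normalized
  expect_true("Cl" %in% toks)
  expect_false(any(toks == ")"))
  # every input character consumed exactly once
  expect_equal(sum(nchar(toks)), nchar("O=C(O)C(Oc1ccc(cc1C)Cl)C"))
})

test_that("multi-character and bracket tokens stay whole", {
  expect_equal(tokenize_smiles("CSSSSC"), c("C", "S", "S", "S", "S", "C"))
  expect_equal(tokenize_smiles("BrCCl"), c("Br", "C", "Cl"))
  expect_equal(tokenize_smiles("C[N+]C"), c("C", "[N+]", "C"))
  expect_equal(tokenize_smiles("C@@H"), c("C", "@@", "H"))
  expect_equal(tokenize_smiles("C%12C"), c("C", "%12", "C"))
  # lowercase aromatic distinct from uppercase aliphatic
  expect_false(identical(tokenize_smiles("c"), tokenize_smiles("C")))
})

test_that("tokenizer rejects bad input with position information", {
  expect_error(tokenize_smiles(""), class = "cwqsar_input_error")
  expect_error(tokenize_smiles("C C"), "position 2", class = "cwqsar_input_error")
  expect_error(tokenize_smiles("C[NH"), class = "cwqsar_input_error")
  expect_error(tokenize_smiles("C%1"), class = "cwqsar_input_error")
})

test_that("pair attributes are unordered and count tokens minus one", {
  toks <- tokenize_smiles("O=C(O)C(Oc1ccc(cc1C)Cl)C")
  pairs <- pair_attributes(toks)
  expect_length(pairs, 22L)
  # canonical form is order-independent
  expect_equal(pair_key("O", "="), pair_key("=", "O"))
  expect_equal(pair_attributes(c("C")), character(0))
  # "C(C)C" after normalization: all four adjacent pairs collapse to {C,(}
  p <- pair_attributes(tokenize_smiles("C(C)C"))
  expect_equal(unique(p), pair_key("C", "("))
  expect_length(p, 4L)
})

test_that("pair rendering puts the higher-character-code token first", {
  expect_equal(render_attribute(pair_key("O", "="), "pair"), "O...=.......")
  expect_equal(render_attribute(pair_key("=", "C"), "pair"), "C...=.......")
  expect_equal(render_attribute(pair_key("c", "O"), "pair"), "c...O.......")
  expect_equal(render_attribute(pair_key("Cl", "("), "pair"), "Cl..(.......")
  expect_equal(render_attribute("Cl", "single"), "Cl..........")
})

test_that("dictionary counts compounds per block and blocks rare attributes", {
  ds <- qsar_dataset(
    id = paste0("m", 1:5),
    smiles = c("CCO", "CCN", "CO", "NN", "OS"),
    endpoint = 1:5,
    set = c("active", "active", "active", "passive", "calibration"))
  dict <- build_attribute_dictionary(ds, T = 3)
  # brute-force recount: 'C' occurs in actives m1, m2, m3
  expect_equal(dict$n_active[dict$key == "C"], 3L)
  expect_false(dict$blocked[dict$key == "C"])
  # 'O' occurs in 2 actives only -> blocked at T = 3
  expect_equal(dict$n_active[dict$key == "O"], 2L)
  expect_true(dict$blocked[dict$key == "O"])
  expect_equal(dict$n_passive[dict$key == "N"], 1L)
  expect_equal(dict$n_calibration[dict$key == "S"], 1L)
  # T = 1: only attributes absent from active training are blocked
  d1 <- build_attribute_dictionary(ds, T = 1)
  expect_equal(d1$blocked, d1$n_active == 0L)
  # counts are per-compound, not per-occurrence: 'C' twice in "CCO" counts once
  expect_equal(dict$n_active[dict$key == "C"], 3L)
})

test_that("dictionary is invariant to record order and requires actives", {
  ds <- make_toy_dataset(n = 20, seed = 7)
  dict1 <- build_attribute_dictionary(ds, T = 2)
  perm <- rev(seq_len(nrow(ds)))
  ds2 <- suppressWarnings(qsar_dataset(ds$id[perm], ds$smiles[perm],
                                       ds$endpoint[perm], ds$set[perm]))
  dict2 <- build_attribute_dictionary(ds2, T = 2)
  expect_equal(dict1$key, dict2$key)
  expect_equal(dict1$n_active, dict2$n_active)
  expect_equal(dict1$blocked, dict2$blocked)
  ds$set <- "unassigned"
  expect_error(build_attribute_dictionary(ds, T = 3), class = "cwqsar_config_error")
})

test_that("tokenization is deterministic and pair count is tokens minus one", {
  ds <- generate_dataset(generator_spec(n_compounds = 25, seed = 11))
  for (s in ds$smiles) {
    t1 <- tokenize_smiles(s)
    expect_identical(t1, tokenize_smiles(s))
    expect_gte(length(t1), 1L)
    expect_length(pair_attributes(t1), length(t1) - 1L)
  }
})
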