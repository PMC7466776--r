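# pinned fixture: every row of the bundled catalog
.pinned <- read.csv(text = "
drug,multiplex_allowed,half_life_min,t_imax_min,q_max,concentration
amiodarone,yes,60,15,100,12
amoxicilin,yes,75,17,250,20
ceftazidime,yes,180,45,500,42
clindamycin,yes,180,45,30,38
clonidine,yes,40,20,15,10
dexmedetomidine,yes,120,15,6,8
dobutamine,no,2,NA,NA,5
dopamine,no,2,NA,NA,4
epinephrine/adrenalin,no,2,NA,NA,0.1
esomeprazole,yes,120,100,4,1.6
fentanyl,yes,20,10,25,0.05
phenylephrine,no,4,1,15,0.1
flucloxacillin,yes,120,30,500,50
furosemide,yes,60,30,20,5
gentamycin,yes,120,15,33,1
heparin,yes,15,30,1500,400
hydrocortisone,yes,180,90,50,4
insulin,undetermined,15,15,0.8,1
potassium chloride,yes,60,30,0.3,1
s-ketamine,yes,10,5,5,5
methylprednisolone,yes,120,90,30,60
magnesium sulfate,yes,60,60,200,100
midazolam,yes,15,25,2,2
milrinone,yes,140,30,0.3,0.2
morphine,yes,20,15,4,1
nicardipine,yes,30,30,0.5,1
nitroglycerin,no,15,7,0.5,0.5
norepinephrine/noradrenalin,no,2,NA,NA,0.1
paracetamol,yes,120,60,60,10
propofol,yes,15,4,200,20
sufentanil,yes,30,30,25,10
tacrolimus,yes,240,60,7,40
vancomycin,yes,120,60,10,40
tobramycin,yes,120,15,8,6
", stringsAsFactors = FALSE)

test_that("bundled catalog reproduces every pinned parameter", {
  cat_ <- default_catalog()
  expect_equal(nrow(cat_), 34)
  for (i in seq_len(nrow(.pinned))) {
    row <- catalog_drug(cat_, .pinned$drug[i])
    expect_false(is.null(row), info = .pinned$drug[i])
    expect_identical(row$multiplex_allowed, .pinned$multiplex_allowed[i],
                     info = .pinned$drug[i])
    expect_equal(row$half_life_min, .pinned$half_life_min[i], info = .pinned$drug[i])
    expect_equal(row$t_imax_min, .pinned$t_imax_min[i], info = .pinned$drug[i])
    expect_equal(row$q_max, .pinned$q_max[i], info = .pinned$drug[i])
    expect_equal(row$concentration, .pinned$concentration[i], info = .pinned$drug[i])
  }
})

test_that("interruption-forbidden drugs have no interruption time", {
  cat_ <- default_catalog()
  nor <- catalog_drug(cat_, "norepinephrine/noradrenalin")
  expect_identical(nor$multiplex_allowed, "no")
  expect_true(is.na(nor$t_imax_min))
  expect_true(is.na(nor$q_max_ml_h))
  ami <- catalog_drug(cat_, "amiodarone")
  expect_equal(ami$t_imax_min, 15)
  expect_equal(ami$q_max, 100)
})

test_that("volumetric rate limits match hand-computed (rate / concentration) * 60", {
  cat_ <- default_catalog()
  expected <- c(amiodarone = 500, amoxicilin = 750, ceftazidime = 500 / 42 * 60,
                clindamycin = 30 / 38 * 60, clonidine = 90, dexmedetomidine = 45,
                esomeprazole = 150, fentanyl = 30, flucloxacillin = 600,
                furosemide = 240, gentamycin = 1980, heparin = 225,
                hydrocortisone = 750, insulin = 48, `potassium chloride` = 18,
                `s-ketamine` = 60, methylprednisolone = 30,
                `magnesium sulfate` = 120, midazolam = 60, milrinone = 90,
                morphine = 240, nicardipine = 30, paracetamol = 360,
                propofol = 600, sufentanil = 150, tacrolimus = 10.5,
                tobramycin = 80, vancomycin = 15,
                phenylephrine = 9, nitroglycerin = 60)
  for (d in names(expected)) {
    expect_equal(catalog_drug(cat_, d)$q_max_ml_h, unname(expected[d]), info = d)
  }
  # cross-base conversion: fentanyl prints ug/min against mg/ml
  expect_equal(q_max_to_ml_h(25, "ug/min", 0.05, "mg/ml"), 30)
})

test_that("loader validates schema, values and units", {
  hdr_only <- tempfile(fileext = ".csv")
  writeLines(paste(c("drug", "multiplex_allowed", "half_life_min", "t_imax_min",
                     "q_max", "q_max_unit", "concentration", "conc_unit",
                     "category"), collapse = ","), hdr_only)
  expect_equal(nrow(load_catalog(hdr_only)), 0)

  no_col <- tempfile(fileext = ".csv")
  writeLines(c("drug,multiplex_allowed", "x,yes"), no_col)
  expect_error(load_catalog(no_col), "half_life_min", class = "mux_schema_error")

  bad <- tiny_catalog("okdrug")
  df <- as.data.frame(bad)[, !(names(bad) %in% "q_max_ml_h")]
  df$half_life_min <- -3
  f <- tempfile(fileext = ".csv"); write.csv(df, f, row.names = FALSE)
  expect_error(load_catalog(f), "okdrug.*half_life", class = "mux_validation_error")

  expect_error(q_max_to_ml_h(1, "mg/min", 1, "mmol/ml"), class = "mux_unit_error")
  expect_error(q_max_to_ml_h(1, "stones/min", 1, "mg/ml"), class = "mux_unit_error")
})

test_that("catalogs round-trip through both dialects", {
  cat_ <- default_catalog()
  f <- tempfile(fileext = ".csv")
  write_catalog(cat_, f)
  again <- load_catalog(f)
  expect_equal(as.data.frame(again), as.data.frame(cat_))

  # keyvalue dialect
  recs <- lapply(seq_len(nrow(cat_)), function(i) {
    r <- as.list(as.data.frame(cat_)[i, setdiff(names(cat_), c("drug", "q_max_ml_h"))])
    r$t_imax_min <- if (is.na(r$t_imax_min)) 0 else r$t_imax_min
    r[!vapply(r, function(v) is.na(v) || identical(v, ""), logical(1))]
  })
  names(recs) <- cat_$drug
  fy <- tempfile(fileext = ".yaml")
  yaml::write_yaml(recs, fy)
  again2 <- load_catalog(fy, dialect = "keyvalue")
  again2 <- again2[match(cat_$drug, again2$drug), ]
  expect_equal(again2$t_imax_min, cat_$t_imax_min)
  expect_equal(again2$q_max_ml_h, cat_$q_max_ml_h)
})

test_that("multiplex eligibility is conservative", {
  cat_ <- default_catalog()
  expect_true(is_multiplexable(cat_, "propofol"))
  expect_false(is_multiplexable(cat_, "insulin"))        # undetermined
  expect_false(is_multiplexable(cat_, "norepinephrine/noradrenalin"))
  expect_false(is_multiplexable(cat_, "not-a-drug"))
  expect_identical(drug_category(cat_, "not-a-drug"), "other")
  expect_identical(drug_category(cat_, "insulin"), "dedicated_lumen")
})
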