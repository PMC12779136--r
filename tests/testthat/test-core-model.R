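# Model and expression-matrix I/O: JSON and SBML readers, validation,
# round trips, and the zero-gene filter.

test_that("toy network round-trips through COBRA-style JSON", {
  net <- build_toy_network()
  path <- withr::local_tempfile(fileext = ".json")
  write_metabolic_model(net, path)
  net2 <- read_metabolic_model(path, format = "json")
  expect_equal(net2$reactions$id, net$reactions$id)
  expect_equal(net2$reactions$lower_bound, net$reactions$lower_bound)
  expect_equal(net2$reactions$upper_bound, net$reactions$upper_bound)
  expect_equal(net2$objective, net$objective)
  expect_equal(net2$metabolites$tag, net$metabolites$tag)
  for (k in seq_len(nrow(net$reactions))) {
    s1 <- net$reactions$stoichiometry[[k]]
    s2 <- net2$reactions$stoichiometry[[k]]
    expect_equal(s2[names(s1)], s1, info = net$reactions$id[k])
  }
  # GPR text survives (parse-equality)
  for (k in seq_len(nrow(net$reactions))) {
    expect_equal(unclass(net2$reactions$gpr[[k]]),
                 unclass(net$reactions$gpr[[k]]))
  }
})

test_that("JSON reader caps infinite bounds and flags structural errors", {
  path <- withr::local_tempfile(fileext = ".json")
  doc <- list(
    id = "t",
    metabolites = list(list(id = "A", compartment = "c")),
    reactions = list(
      list(id = "R1", metabolites = list(A = 1), lower_bound = 0,
           upper_bound = "inf", objective_coefficient = 1)
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  net <- read_metabolic_model(path)
  expect_equal(net$reactions$upper_bound, 1000)

  doc$reactions[[1]]$metabolites <- list(X = 1)
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_metabolic_model(path), "X")

  doc$reactions[[1]]$metabolites <- list(A = 1)
  doc$reactions[[1]]$objective_coefficient <- 0
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_metabolic_model(path), "objective")
})

test_that("SBML L3+FBC subset reads bounds, GPRs and the objective", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1">
 <model id="mini" fbc:strict="true">
  <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="c" constant="false"
            hasOnlySubstanceUnits="false" boundaryCondition="false"/>
   <species id="B" compartment="c" constant="false"
            hasOnlySubstanceUnits="false" boundaryCondition="false"/>
  </listOfSpecies>
  <listOfParameters>
   <parameter id="lb0" value="0" constant="true"/>
   <parameter id="ub10" value="10" constant="true"/>
   <parameter id="ubInf" value="INF" constant="true"/>
  </listOfParameters>
  <fbc:listOfGeneProducts>
   <fbc:geneProduct fbc:id="g_hk1" fbc:label="HK1"/>
   <fbc:geneProduct fbc:id="g_hk2" fbc:label="HK2"/>
  </fbc:listOfGeneProducts>
  <listOfReactions>
   <reaction id="IN" reversible="false" fast="false"
             fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ub10">
    <listOfProducts><speciesReference species="A" stoichiometry="1" constant="true"/></listOfProducts>
   </reaction>
   <reaction id="CONV" reversible="false" fast="false"
             fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubInf">
    <listOfReactants><speciesReference species="A" stoichiometry="1" constant="true"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="1" constant="true"/></listOfProducts>
    <fbc:geneProductAssociation>
     <fbc:or>
      <fbc:geneProductRef fbc:geneProduct="g_hk1"/>
      <fbc:geneProductRef fbc:geneProduct="g_hk2"/>
     </fbc:or>
    </fbc:geneProductAssociation>
   </reaction>
   <reaction id="OUT" reversible="false" fast="false"
             fbc:lowerFluxBound="lb0" fbc:upperFluxBound="ubInf">
    <listOfReactants><speciesReference species="B" stoichiometry="1" constant="true"/></listOfReactants>
   </reaction>
  </listOfReactions>
  <fbc:listOfObjectives fbc:activeObjective="obj">
   <fbc:objective fbc:id="obj" fbc:type="maximize">
    <fbc:listOfFluxObjectives>
     <fbc:fluxObjective fbc:reaction="OUT" fbc:coefficient="1"/>
    </fbc:listOfFluxObjectives>
   </fbc:objective>
  </fbc:listOfObjectives>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, path)
  net <- read_metabolic_model(path, format = "sbml")
  expect_equal(nrow(net$reactions), 3)
  expect_equal(net$objective, "OUT")
  expect_equal(net$reactions$upper_bound[net$reactions$id == "IN"], 10)
  # INF parameter capped at the default bound cap
  expect_equal(net$reactions$upper_bound[net$reactions$id == "CONV"], 1000)
  expect_equal(sort(gpr_genes(net$reactions$gpr[[2]])), c("HK1", "HK2"))
  expect_equal(run_fba(net)$objective_value, 10, tolerance = 1e-8)
})

test_that("expression matrix reader validates and round-trips", {
  net <- build_toy_network()
  m <- simulate_expression(net, phenotype_spec(n_healthy = 2, n_cancer = 2,
                                               n_decoys = 1, seed = 3))
  ep <- withr::local_tempfile(fileext = ".tsv")
  lp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, ep, lp)
  m2 <- read_expression_matrix(ep, lp)
  expect_equal(m2$values, m$values)
  expect_equal(m2$samples, m$samples)

  # negative values rejected with coordinates
  bad <- m$values
  bad[2, 1] <- -1.2
  expect_error(
    expr_matrix(bad, stats::setNames(m$samples$label, m$samples$sample_id)),
    rownames(bad)[2]
  )

  # duplicate sample id in header rejected
  tab <- readLines(ep)
  tab[1] <- sub("C001", "H001", tab[1])
  writeLines(tab, ep)
  expect_error(read_expression_matrix(ep, lp), "H001")
})

test_that("filter_zero_genes removes exactly all-zero rows, idempotently", {
  vals <- rbind(
    gene_a = c(0, 0, 0),
    gene_b = c(0, 0.01, 0),
    gene_c = c(1, 2, 3)
  )
  colnames(vals) <- paste0("s", 1:3)
  labels <- stats::setNames(rep("healthy", 3), colnames(vals))
  m <- expr_matrix(vals, labels)
  f <- filter_zero_genes(m)
  expect_equal(rownames(f$values), c("gene_b", "gene_c"))
  expect_equal(colnames(f$values), colnames(vals))
  # idempotent; identity when nothing is all-zero
  expect_equal(filter_zero_genes(f)$values, f$values)
})
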