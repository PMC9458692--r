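# Toy knowledge graphs emulating the simplified biomedical data models used
# throughout the package's examples and tests: Drugbank/Sider/Diseasome-style
# drugs, diseases, side effects and genes, plus a Bgee-style gene-expression
# branch, and a projects/topics graph with an acronym decoy. All fixtures are
# synthetic stand-ins built in code; none contain real database content.

NS_DRUGBANK <- "http://example.org/drugbank/"
NS_SIDER <- "http://example.org/sider/"
NS_DISEASOME <- "http://example.org/diseasome/"
NS_BGEE <- "http://example.org/bgee/"
NS_CORDIS <- "http://example.org/cordis/"

FIXTURE_PREFIXES <- c(
  drugbank = NS_DRUGBANK, sider = NS_SIDER, diseasome = NS_DISEASOME,
  bgee = NS_BGEE, cordis = NS_CORDIS,
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#"
)

#' Build a named fixture knowledge graph
#'
#' * `fig1_asthma` — one Drug class whose instances reach "asthma" three
#'   ways: as a Disease label (via `possibleDiseaseTarget`), as a Side_Effect
#'   name (via `sideEffect`), and inside a drug description literal (the
#'   minimal-subgraph decoy). The Disease instance is the most central match.
#' * `fig2_biomed` — the integrated four-source model: Bgee-style
#'   Gene/AnatomicalEntity with the disjoint `isExpressedIn`/`isAbsentIn`
#'   pair, Diseasome diseases and genes, Drugbank drugs, Sider drugs and
#'   side effects, inverse `possibleDiseaseTarget`/`possibleDrug` properties
#'   and `sameAs` bridges between the two Drug classes.
#' * `fig3_brca` — `fig2_biomed` plus genes labelled "BRCA1"/"BRCA2" with
#'   associated cancers and their drugs, for the end-to-end walkthrough.
#' * `cordis_decoy` — a central Topic class whose name also occurs as the
#'   acronym of one low-centrality project.
#' * `random` — seeded random graph (see [random_kg()]).
#'
#' @param name Fixture name.
#' @param seed Seed (used by `random`; recorded otherwise).
#' @param ... Passed to [random_kg()] for the `random` fixture.
#' @return A [kg()] object. Same name + seed always yields a byte-identical
#'   N-Triples serialization.
#' @export
build_fixture <- function(name = c(
                            "fig1_asthma", "fig2_biomed", "fig3_brca",
                            "cordis_decoy", "random"
                          ),
                          seed = 1L, ...) {
  name <- match.arg(name)
  switch(name,
    fig1_asthma = fixture_fig1(),
    fig2_biomed = fixture_fig2(),
    fig3_brca = fixture_fig3(),
    cordis_decoy = fixture_cordis(),
    random = random_kg(seed = seed, ...)
  )
}

# triple-row helpers
t_iri <- function(s, p, o) {
  tibble::tibble(
    subject = s, predicate = p, object = o,
    object_kind = "iri", datatype = NA_character_, lang = NA_character_
  )
}
t_lit <- function(s, p, o, datatype = NA_character_) {
  tibble::tibble(
    subject = s, predicate = p, object = o,
    object_kind = "literal", datatype = datatype, lang = NA_character_
  )
}

# A drug with label/description, typed under `cls`.
drug_rows <- function(iri, cls, label, description) {
  dplyr::bind_rows(
    t_iri(iri, RDF_TYPE, cls),
    t_lit(iri, RDFS_LABEL, label),
    if (!is.null(description)) t_lit(iri, DCT_DESCRIPTION, description)
  )
}

fixture_fig1 <- function() {
  db <- function(x) paste0(NS_DRUGBANK, x)
  ds <- function(x) paste0(NS_DISEASOME, x)
  sd <- function(x) paste0(NS_SIDER, x)
  pdt <- ds("possibleDiseaseTarget")
  pd <- ds("possibleDrug")
  rows <- dplyr::bind_rows(
    drug_rows(db("DB01001"), db("drugs"), "Salbutamol",
      "A short acting beta agonist used to treat asthma and bronchospasm."),
    drug_rows(db("DB00277"), db("drugs"), "Theophylline",
      "A methyl xanthine derivative used in the management of airway obstruction."),
    drug_rows(db("DB00471"), db("drugs"), "Montelukast",
      "A leukotriene receptor antagonist for maintenance therapy of chronic respiratory conditions."),
    drug_rows(db("DB00635"), db("drugs"), "Prednisone",
      "A synthetic glucocorticoid used for its potent anti inflammatory effects."),
    drug_rows(db("DB00571"), db("drugs"), "Propranolol",
      "A non selective beta blocker used for hypertension and tremor."),
    t_iri(ds("asthma"), RDF_TYPE, ds("diseases")),
    t_lit(ds("asthma"), RDFS_LABEL, "asthma"),
    t_iri(ds("migraine"), RDF_TYPE, ds("diseases")),
    t_lit(ds("migraine"), RDFS_LABEL, "migraine"),
    # four drugs target the asthma Disease: the central interpretation
    t_iri(db("DB01001"), pdt, ds("asthma")),
    t_iri(db("DB00277"), pdt, ds("asthma")),
    t_iri(db("DB00471"), pdt, ds("asthma")),
    t_iri(db("DB00635"), pdt, ds("asthma")),
    t_iri(db("DB00571"), pdt, ds("migraine")),
    t_iri(ds("asthma"), pd, db("DB01001")),
    t_iri(ds("asthma"), pd, db("DB00277")),
    t_iri(ds("asthma"), pd, db("DB00471")),
    t_iri(ds("asthma"), pd, db("DB00635")),
    t_iri(ds("migraine"), pd, db("DB00571")),
    # one drug has asthma as a recorded side effect: the opposite reading
    t_iri(sd("C0004096"), RDF_TYPE, sd("side_effects")),
    t_lit(sd("C0004096"), sd("sideEffectName"), "asthma"),
    t_iri(db("DB00571"), sd("sideEffect"), sd("C0004096"))
  )
  kg(rows, prefixes = FIXTURE_PREFIXES)
}

fixture_fig2 <- function() {
  db <- function(x) paste0(NS_DRUGBANK, x)
  ds <- function(x) paste0(NS_DISEASOME, x)
  sd <- function(x) paste0(NS_SIDER, x)
  bg <- function(x) paste0(NS_BGEE, x)
  pdt <- ds("possibleDiseaseTarget")
  pd <- ds("possibleDrug")
  disease <- function(iri, label) {
    dplyr::bind_rows(
      t_iri(ds(iri), RDF_TYPE, ds("diseases")),
      t_lit(ds(iri), RDFS_LABEL, label)
    )
  }
  target <- function(drug, dis) {
    dplyr::bind_rows(
      t_iri(db(drug), pdt, ds(dis)),
      t_iri(ds(dis), pd, db(drug))
    )
  }
  rows <- dplyr::bind_rows(
    drug_rows(db("DB01050"), db("drugs"), "Ibuprofen",
      "A nonsteroidal anti inflammatory agent with analgesic properties used in the therapy of rheumatism."),
    drug_rows(db("DB01001"), db("drugs"), "Salbutamol",
      "A short acting beta agonist used to treat asthma and bronchospasm."),
    drug_rows(db("DB00277"), db("drugs"), "Theophylline",
      "A methyl xanthine derivative used in the management of airway obstruction."),
    drug_rows(db("DB00471"), db("drugs"), "Montelukast",
      "A leukotriene receptor antagonist for maintenance therapy of chronic respiratory conditions."),
    drug_rows(db("DB00675"), db("drugs"), "Tamoxifen",
      "An antineoplastic agent used in the management of estrogen receptor positive tumours."),
    drug_rows(db("DB00958"), db("drugs"), "Carboplatin",
      "A platinum based antineoplastic agent used for carcinoma of the ovary."),
    disease("asthma", "asthma"),
    disease("migraine", "migraine"),
    disease("breast_cancer", "breast cancer"),
    disease("ovarian_cancer", "ovarian cancer"),
    disease("stroke", "stroke"),
    target("DB01001", "asthma"),
    target("DB00277", "asthma"),
    target("DB00471", "asthma"),
    target("DB01050", "migraine"),
    target("DB00675", "breast_cancer"),
    target("DB00958", "ovarian_cancer"),
    # diseasome gene branch
    t_iri(ds("PIK3CA"), RDF_TYPE, ds("genes")),
    t_lit(ds("PIK3CA"), RDFS_LABEL, "PIK3CA"),
    t_iri(ds("PIK3CA"), ds("associatedWith"), ds("breast_cancer")),
    # sider branch: drugs, side effects, sameAs bridges
    drug_rows(sd("ibuprofen"), sd("drugs"), "Ibuprofen", NULL),
    drug_rows(sd("salbutamol"), sd("drugs"), "Salbutamol", NULL),
    t_iri(sd("ibuprofen"), OWL_SAMEAS, db("DB01050")),
    t_iri(sd("salbutamol"), OWL_SAMEAS, db("DB01001")),
    t_iri(sd("C0038454"), RDF_TYPE, sd("side_effects")),
    t_lit(sd("C0038454"), sd("sideEffectName"), "Stroke"),
    t_iri(sd("ibuprofen"), sd("sideEffect"), sd("C0038454")),
    t_iri(sd("C0018681"), RDF_TYPE, sd("side_effects")),
    t_lit(sd("C0018681"), sd("sideEffectName"), "Headache"),
    t_iri(sd("salbutamol"), sd("sideEffect"), sd("C0018681")),
    t_iri(sd("C0038454"), OWL_SAMEAS, ds("stroke")),
    # bgee branch: disjoint expression properties between one class pair
    t_iri(bg("ENSG00000244734"), RDF_TYPE, bg("Gene")),
    t_lit(bg("ENSG00000244734"), RDFS_LABEL, "HBB"),
    t_lit(bg("ENSG00000244734"), DCT_DESCRIPTION, "hemoglobin subunit beta"),
    t_iri(bg("ENSG00000157764"), RDF_TYPE, bg("Gene")),
    t_lit(bg("ENSG00000157764"), RDFS_LABEL, "BRAF"),
    t_iri(bg("UBERON_0002048"), RDF_TYPE, bg("AnatomicalEntity")),
    t_lit(bg("UBERON_0002048"), RDFS_LABEL, "lung"),
    t_iri(bg("UBERON_0000955"), RDF_TYPE, bg("AnatomicalEntity")),
    t_lit(bg("UBERON_0000955"), RDFS_LABEL, "brain"),
    t_iri(bg("ENSG00000244734"), bg("isExpressedIn"), bg("UBERON_0002048")),
    t_iri(bg("ENSG00000244734"), bg("isAbsentIn"), bg("UBERON_0000955")),
    t_iri(bg("ENSG00000157764"), bg("isExpressedIn"), bg("UBERON_0000955"))
  )
  kg(rows, prefixes = FIXTURE_PREFIXES)
}

fixture_fig3 <- function() {
  ds <- function(x) paste0(NS_DISEASOME, x)
  gene <- function(iri, label, diseases) {
    dplyr::bind_rows(
      t_iri(ds(iri), RDF_TYPE, ds("genes")),
      t_lit(ds(iri), RDFS_LABEL, label),
      dplyr::bind_rows(lapply(diseases, function(d) t_iri(ds(iri), ds("associatedWith"), ds(d))))
    )
  }
  rows <- dplyr::bind_rows(
    fixture_fig2(),
    gene("BRCA1", "BRCA1", "breast_cancer"),
    gene("BRCA2", "BRCA2", c("breast_cancer", "ovarian_cancer"))
  )
  kg(rows, prefixes = FIXTURE_PREFIXES)
}

fixture_cordis <- function() {
  co <- function(x) paste0(NS_CORDIS, x)
  project <- function(iri, label, acronym, topic) {
    dplyr::bind_rows(
      t_iri(co(iri), RDF_TYPE, co("projects")),
      t_lit(co(iri), RDFS_LABEL, label),
      t_lit(co(iri), co("acronym"), acronym),
      t_iri(co(iri), co("projectTopic"), co(topic))
    )
  }
  topic <- function(iri, label) {
    dplyr::bind_rows(
      t_iri(co(iri), RDF_TYPE, co("topics")),
      t_lit(co(iri), RDFS_LABEL, label)
    )
  }
  rows <- dplyr::bind_rows(
    topic("T001", "Health and wellbeing"),
    topic("T002", "Climate and energy"),
    topic("T003", "Digital infrastructure"),
    project("P001", "Adaptive immune atlas", "ADIMA", "T001"),
    project("P002", "Wind farm resilience", "WINDRES", "T002"),
    project("P003", "Edge computing fabric", "EDGEFAB", "T003"),
    project("P004", "Microbiome mapping", "MICROMAP", "T001"),
    project("P005", "Testing of photonic interconnect circuits", "Topic", "T003"),
    project("P006", "Solar grid storage", "SOLSTORE", "T002"),
    project("P007", "Rare disease registry", "RAREG", "T001"),
    project("P008", "Urban air quality", "URBAQ", "T002")
  )
  kg(rows, prefixes = FIXTURE_PREFIXES)
}

#' Generate a random typed knowledge graph
#'
#' Seeded generator for property-style tests: random classes and properties
#' with instance-level links respecting the generated domains/ranges, random
#' short labels, a guaranteed multigraph property pair between one class
#' pair, and optional injection of untyped instances (to exercise indexer
#' warnings) and verbose literals (to exercise the first-sentence cap).
#'
#' @param seed Integer seed; the generator restores the caller's RNG state.
#' @param n_classes,n_properties,n_instances Graph size knobs.
#' @param link_per_instance Mean outgoing object links per instance.
#' @param p_untyped Fraction of instances left untyped.
#' @param p_verbose Fraction of instances given a long description literal.
#' @param vocabulary Words labels are drawn from.
#' @return A [kg()] object.
#' @export
random_kg <- function(seed = 1L, n_classes = 4L, n_properties = 5L,
                      n_instances = 30L, link_per_instance = 2,
                      p_untyped = 0, p_verbose = 0,
                      vocabulary = c(
                        "alpha", "beta", "gamma", "delta", "kappa", "sigma",
                        "omega", "zeta", "lambda", "theta"
                      )) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  ns <- "http://example.org/rand/"
  classes <- paste0(ns, "Class", seq_len(n_classes))
  # property domain/range assignments; the first two share a class pair
  dom <- sample(classes, n_properties, replace = TRUE)
  rng <- sample(classes, n_properties, replace = TRUE)
  if (n_properties >= 2 && n_classes >= 2) {
    dom[2] <- dom[1]
    rng[2] <- rng[1]
    if (dom[1] == rng[1]) rng[1:2] <- setdiff(classes, dom[1])[1]
  }
  properties <- paste0(ns, "prop", seq_len(n_properties))
  inst_class <- sample(seq_len(n_classes), n_instances, replace = TRUE)
  instances <- paste0(ns, "inst", seq_len(n_instances))
  untyped <- stats::runif(n_instances) < p_untyped
  rows <- list()
  add <- function(x) rows[[length(rows) + 1L]] <<- x
  for (i in seq_len(n_instances)) {
    if (!untyped[i]) add(t_iri(instances[i], RDF_TYPE, classes[inst_class[i]]))
    label <- paste(sample(vocabulary, sample(1:3, 1)), collapse = " ")
    add(t_lit(instances[i], RDFS_LABEL, label))
    if (stats::runif(1) < p_verbose) {
      long <- paste(sample(vocabulary, 40, replace = TRUE), collapse = " ")
      add(t_lit(instances[i], DCT_DESCRIPTION, paste0(long, ".")))
    }
    n_links <- stats::rpois(1, link_per_instance)
    for (k in seq_len(n_links)) {
      p <- sample(seq_len(n_properties), 1)
      if (classes[inst_class[i]] != dom[p] && !untyped[i]) next
      targets <- instances[inst_class == match(rng[p], classes) & !untyped]
      if (length(targets) == 0) next
      add(t_iri(instances[i], properties[p], sample(targets, 1)))
    }
  }
  kg(dplyr::bind_rows(rows), prefixes = c(rand = ns))
}
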