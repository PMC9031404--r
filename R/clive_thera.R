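#' The scripted therapist-client worked example
#'
#' Builds the package's packaged dyadic fixture: a client (Clive) whose
#' distressing belief "I am stupid" forms a small autocatalytic cluster, and
#' a therapist (Thera) who dissolves it and catalyses adaptive new beliefs
#' over one session. The session log scripts, step by step:
#'
#' * **1a/1b** — the memories of a bad grade (`GC`) and a lost job (`PC`),
#'   catalysed by the incident of being called a moron (`mC`), are
#'   redescribed into the derived belief `b1C` ("I am stupid"); a supporting
#'   confirmation-bias event strengthens that belief-RAF.
#' * **intake** — Clive's self-account `CC` is socially transmitted to Thera
#'   (`CT`), seeding her mental model of him.
#' * **2/3** — Thera's praise (`BT`, "you're a brilliant problem solver") is
#'   transmitted to Clive as `BC`, which inhibits the belief-RAF: its impact
#'   weight strictly decreases.
#' * **4** — Thera's humorous reframe of her own clumsiness (`LT`) is
#'   transmitted as `LC`.
#' * **5** — her prompt to seek alternative explanations (`qT`) is
#'   transmitted; housed in Clive's foodset so it can act as a catalyst.
#' * **6a/6b** — `GC` is redescribed, catalysed by `qT`, into the joke/
#'   reinterpretation `VC` ("I spent all my time playing video games"); the
#'   joke further inhibits the belief-RAF.
#' * **7a/7b** — Thera's laughter (`lT`) is transmitted; the joke, now also a
#'   heard utterance `JC`, is redescribed under `lT` into the derived belief
#'   `b2C` ("I am funny"), which Thera then reinforces.
#'
#' With `joke_as_foodset = TRUE` (the default) the spoken joke `JC` is a
#' distinct direct-experience foodset item, so the final client system has
#' three irreducible RAFs — the belief cluster, the joke, and the new "I am
#' funny" belief — whose union is the maxRAF. With `FALSE`, joke and
#' reinterpretation are a single derived item (`VC`) that feeds the final
#' reaction, giving a chained structure with two irrRAFs. The two readings
#' reflect a genuine ambiguity in the source narrative (see the package
#' vignette); the default reproduces the three-irrRAF structure.
#'
#' @param joke_as_foodset whether the spoken joke re-enters the client's
#'   foodset as a separate item (see Details).
#' @param alpha,beta impact-weight update parameters, see [mind()].
#' @return a [dyad()] whose log has been applied (and which [replay()]
#'   reconstructs exactly).
#' @examples
#' d <- build_clive_thera()
#' irr_rafs(mind_to_system(d$client))
#' @export
build_clive_thera <- function(joke_as_foodset = TRUE, alpha = 0.5, beta = 0.5) {
  clive <- mind("Clive", alpha = alpha, beta = beta)
  clive <- add_foodset_item(clive, "GC", "got a D- in high-school math")
  clive <- add_foodset_item(clive, "PC", "did not get the job he prepared for")
  clive <- add_foodset_item(clive, "mC", "wife called him a 'moron' (catalyzing incident)")
  clive <- add_foodset_item(clive, "CC", "Clive's account of himself and his concerns")

  thera <- mind("Thera", alpha = alpha, beta = beta)
  thera <- add_foodset_item(thera, "KT", "clinical knowledge of social anxiety and its treatment")

  d <- dyad(client = clive, therapist = thera)

  # Step 1a/1b: formation of the distressing belief, then its reinforcement
  # by confirmation bias (the thick oval).
  d <- dyad_event(d, "react", "Clive", list(
    reactants = c("GC", "PC"), catalyst = "mC",
    product = "b1C", label = "I am stupid", reaction_id = "r1"), step = "1a")
  d <- dyad_event(d, "reweight", "Clive", list(raf = "r1"), step = "1b")

  # Intake: Clive's self-description is socially transmitted to Thera.
  d <- dyad_event(d, "transmit", "Clive", list(
    item = "CC", to = "Thera", new_id = "CT",
    label = "Thera's mental model of Clive"), step = "intake")

  # Step 2: praise born in Thera's mind, transmitted to Clive's foodset.
  d <- dyad_event(d, "add", "Thera", list(
    id = "BT", label = "observation: Clive brilliantly fixed the chair"),
    step = "2")
  d <- dyad_event(d, "transmit", "Thera", list(
    item = "BT", to = "Clive", new_id = "BC",
    label = "someone thinks I'm brilliant"), step = "2")

  # Step 3: the praise is inconsistent with the belief-RAF and inhibits it.
  d <- dyad_event(d, "inhibit", "Clive", list(item = "BC", raf = "r1"),
                  step = "3")

  # Step 4: self-disclosure — the humour reframe is modelled, then transmitted.
  d <- dyad_event(d, "add", "Thera", list(
    id = "LT", label = "laughing off 'I am clumsy' (humour reframe)"),
    step = "4")
  d <- dyad_event(d, "transmit", "Thera", list(
    item = "LT", to = "Clive", new_id = "LC",
    label = "inadequacy can be laughed off"), step = "4")

  # Step 5: the prompt to seek alternative explanations, transmitted so it
  # can act as a catalyst inside Clive's network.
  d <- dyad_event(d, "add", "Thera", list(
    id = "qT", label = "question: other reasons for the bad grade?"),
    step = "5")
  d <- dyad_event(d, "transmit", "Thera", list(
    item = "qT", to = "Clive"), step = "5")

  # Step 6a/6b: the joke — a reinterpretation of the bad grade — and its
  # inhibitory effect on the belief-RAF (it depletes the reactant's support).
  d <- dyad_event(d, "react", "Clive", list(
    reactants = "GC", catalyst = "qT",
    product = "VC", label = "joke: I spent all my time playing video games",
    reaction_id = "r2"), step = "6a")
  d <- dyad_event(d, "inhibit", "Clive", list(item = "VC", raf = "r1"),
                  step = "6b")

  # Step 7a/7b: Thera's laughter catalyses the new adaptive belief.
  d <- dyad_event(d, "add", "Thera", list(
    id = "lT", label = "Thera laughs at Clive's joke"), step = "7a")
  d <- dyad_event(d, "transmit", "Thera", list(
    item = "lT", to = "Clive"), step = "7a")
  joke_reactant <- "VC"
  if (joke_as_foodset) {
    d <- dyad_event(d, "add", "Clive", list(
      id = "JC", label = "the joke as heard utterance"), step = "7a")
    joke_reactant <- "JC"
  }
  d <- dyad_event(d, "react", "Clive", list(
    reactants = joke_reactant, catalyst = "lT",
    product = "b2C", label = "I am funny", reaction_id = "r3"), step = "7b")
  # Thera reinforces the adaptive cluster; under the chained (one-item)
  # reading {r3} is not itself irreducible, so the joke-RAF carries the weight.
  d <- dyad_event(d, "reweight", "Clive",
                  list(raf = if (joke_as_foodset) "r3" else "r2"), step = "7b")

  d
}
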