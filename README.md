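# rafnet

Detection and analysis of **RAF sets** — Reflexively Autocatalytic and
F-generated sets — in catalytic reaction systems, with a cognitive
instantiation in which the "molecules" are mental representations and the
"reactions" are acts of representational redescription.

## The model

A catalytic reaction system is a tuple Q = (X, R, C, F): a set X of entity
types, a set R of reactions (each consuming a reactant multiset and producing
a product multiset over X), a catalysis relation C ⊆ X × R, and a foodset
F ⊆ X of types present from the outset. A non-empty subset R′ ⊆ R is a
**RAF** when

1. **RA** — every reaction in R′ is catalyzed by at least one type that is
   produced by R′ or lies in F, and
2. **F-generated** — every reactant of every reaction in R′ lies in the
   closure of F under R′ (the least set obtained by repeatedly firing
   reactions whose reactants are available).

RAFs are closed under union, so a system containing any RAF contains a unique
maximal one, the **maxRAF**; the RAFs inside it (**subRAFs**) form a poset
under inclusion whose minimal elements are the irreducible RAFs
(**irrRAFs**). A **co-RAF** is a non-RAF set that yields a RAF when united
with a given RAF. `max_raf()` computes the maxRAF by the standard
polynomial-time interleaved pruning (drop any reaction with an unreachable
reactant or no reachable catalyst, until a fixed point); `all_sub_rafs()` is
an independent exponential brute-force oracle used to certify it.

Two application layers sit on the core:

* **Generators** — `binary_polymer_system()` builds the classic binary
  polymer chemistry (all binary strings up to length n, ligation reactions,
  random catalysis with probability p), and `phase_experiment()` traces the
  sharp no-RAF → RAF phase transition as p grows.
* **Cognitive networks** — a `mind()` holds mental representations
  partitioned into a foodset (innate, socially transmitted, or individually
  learned items) and a foodset-derived set (products of the mind's own
  catalyzed redescriptions, each traceable to foodset sources via
  `provenance_chain()`). Minds are coupled into a `dyad()` with a replayable
  session log; inhibition and support events move per-RAF impact weights
  multiplicatively. `build_clive_thera()` ships a fully scripted
  therapist–client session in which a distressing belief cluster is formed,
  weakened by counter-evidence, and joined by two adaptive new RAFs.

## Worked example

```r
library(rafnet)

q <- parse_system("F: GC, PC, mC\nr1: GC + PC -> b1C\ncat: mC r1")
max_raf(q)
#> <raf_result> |R'| = 1; RA = TRUE; F-generated = TRUE; RAF = TRUE
#>   subset: r1
```

Two adverse memories (`GC`, a failed math class; `PC`, a lost job),
catalyzed by a hurtful incident (`mC`), are redescribed into the derived
belief `b1C` ("I am stupid") — and because the catalyst is in the foodset and
the reactants are available, the single reaction `{r1}` already satisfies
both RAF criteria: the belief is self-sustaining.

Running the full scripted session:

```r
res <- cmd_example("clive-thera")
res$irrRAF_count          # 3 irreducible RAFs in the final client network
res$irrRAFs               # list("r1"), list("r2"), list("r3")
res$belief_raf_trajectory
#>     step     kind weight
#> 1     1a    react  1.000
#> 2     1b reweight  1.500
#> 3 intake transmit  1.500
#> 4      3  inhibit  0.750
#> 5     6a    react  0.750
#> 6     6b  inhibit  0.375
#> 7     7a      add  0.375
#> 8     7b    react  0.375
#> 9     7b reweight  0.375
```

The three irrRAFs are the distressing belief (`r1`), the joke reframing the
bad grade (`r2`), and the new belief "I am funny" (`r3`); their union is the
client's maxRAF. The impact weight of the belief-RAF rises once under
confirmation bias (step 1b) and then falls strictly at each inhibition: the
therapist's praise (step 3) and the client's own joke (step 6b).

A phase-transition curve at desk scale:

```r
phase_experiment(4, 2, c(0, 0.005, 0.02, 0.1, 1), replicates = 10, seed = 99)
#>       p replicates raf_fraction mean_maxraf_size
#> 1 0.000         10          0.0              0.0
#> 2 0.005         10          0.5              1.0
#> 3 0.020         10          1.0             20.4
#> 4 0.100         10          1.0             65.4
#> 5 1.000         10          1.0             68.0
```

## Command line

A thin wrapper over the same functions is installed at
`system.file("cli", "rafnet.R", package = "rafnet")`:

```sh
Rscript rafnet.R analyze system.txt --json-out report.json --dot graph.dot
Rscript rafnet.R example clive-thera --dot panels/
Rscript rafnet.R phase --n 6 --t 2 --p-grid 0:0.05:8 --reps 25 --seed 1 --out phase.tsv
```

Exit codes: 0 ok, 2 parse error, 3 validation error, 4 size cap exceeded.

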