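# htnrec

Hybrid drug recommender for first-line antihypertensive therapy, with a
vignette-panel evaluation framework and a synthetic-EHR benchmark generator.

**Not for clinical use.** The shipped contraindication rule base is a small
synthetic demonstration; its clinical content is illustrative only.

## The problem and the method

Choosing the initial single-drug treatment for newly diagnosed hypertension
(among the five main classes: ACE inhibitors, angiotensin-receptor blockers,
beta blockers, calcium channel blockers, diuretics) has to balance population
evidence with the individual patient's demographics, comorbidities,
comedication and life situation. `htnrec` implements a hybrid clinical
decision support engine that combines:

1. **Neighborhood-based collaborative filtering over routine-care records.**
   A target patient's neighborhood is formed from the training database by
   the simple matching coefficient over K configured attributes,

       eta_j = (1/K) * sum_k s(x_k, x_{k,j}),

   with exact matching for categorical attributes and closed-interval
   matching `|x_k − x_{k,j}| ≤ Δ_k` for numeric ones (default: gender, age
   ± 5 y, BMI ± 2.5 kg/m²). A database patient joins the neighborhood when
   `eta_j = 1` (similar on *all* attributes). Treatment scores are the
   l1-normalized projection through a binary patient–therapy matrix **A**,

       h = eta / ||eta||_1 · A,

   where **A** marks, per patient, either any application of a treatment
   ("pop" mode, popularity ranking) or an application that reached the
   140/90 mmHg blood-pressure endpoint ("mean" mode, outcome ranking).
   Engines: global baseline `RE-glob` (whole database as neighborhood) vs
   personalized `RE-loc`; suffix `-eb` adds the rule-based post-filter.

2. **Evidence-based contraindication rules.** Structured rule records
   (treatment, trigger type ∈ comorbidity/condition/comedication, trigger
   code, level ∈ absolute/relative, source) are retrieved conditional on the
   target's clinical context; options are labeled and — for the `-eb`
   engines — absolutely contraindicated options are removed *before* top-N
   truncation.

3. **Evaluation against an expert panel.** Engine top-N lists are compared
   with one-hot expert choices per case vignette: `agree_all` (mean
   per-expert hit rate), `agree_any` (hit against the union of expert
   choices), `agree_majority` (hit against the majority vote, ties
   included), plus the expert×expert inter-rater matrix.

Training data are longitudinal visit sequences (untreated baseline V0,
follow-ups V1–V4). Only each patient's *initial-treatment episode* — the
maximal contiguous run of visits under the first prescribed treatment —
yields a training point; its outcome is the blood-pressure change from
baseline to the episode's last reading and the dichotomous 140/90 endpoint.

Because such routine-care databases are not publicly available, the package
includes a seeded synthetic-EHR generator with planted subgroup×treatment
effects and planted contraindications, so that recommendation quality is
measurable against a known ground truth.

## Worked example

```r
library(htnrec)

cfg <- generator_config(n_patients = 500, seed = 42)
sim <- generate_training_db(cfg)
db  <- build_training_db(sim$patients, sim$visits)
db
#> <training_db> 500 initial-treatment episodes
#>   treatments: ACE_INHIBITOR=102, ARB=107, BETA_BLOCKER=96, CALCIUM_CHANNEL_BLOCKER=111, DIURETIC=84
#>   endpoint reached: 108/500

target <- list(
  features = list(gender = "F", age = 48),
  context  = list(conditions = "PREGNANCY")
)
schema <- attribute_schema(attr_categorical("gender"), attr_numeric("age", 5))
rec <- recommend(target, db,
                 engine_config(scope = "local", mode = "mean", top_n = 3,
                               post_filter = "absolute", schema = schema),
                 rules = demo_rules())
rec
#> <recommendation> RE-loc-eb — ok
#>   neighborhood: 60 of 500
#>   1. CALCIUM_CHANNEL_BLOCKER  score=0.067 support=18
#>   2. BETA_BLOCKER             score=0.017 support=12
#>   3. DIURETIC                 score=0.017 support=11
```

The 60 neighbors are the women aged 43–53 in the database. Each score is the
fraction of the neighborhood that both received the treatment and reached
140/90 (so `0.067 = 4/60`); the pregnancy context absolutely contraindicates
ACE inhibitors and ARBs (demo rules R1/R3), which the `-eb` post-filter
removed before the top-3 cut. `payload_json(rec)` renders the same result as
the JSON payload a recommendation service would return.

`run_benchmark()` evaluates the four engine variants (`RE-glob`, `RE-loc`,
`RE-glob-eb`, `RE-loc-eb`) for top-1/2/3 against an expert label table, and
the `inst/cli/htnrec.R` script exposes `simulate` / `recommend` /
`evaluate` / `inter-rater` subcommands over a YAML run configuration.

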