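# Full-model transcription layout

The full 96-component DNA damage response model is defined by its published
supplementary table of logical functions, which is not redistributable with
this package. To run the full-model analyses, transcribe it into the native
JSON format and place the files here (or pass explicit paths):

- `ddr_full_model.json` — the 96 components and 98 interaction terms.
  Each component: `name`, `max_level` (2 only for ATM-P, IKK_complex-P and
  IκBα), `default_level` (2 for IκBα, 1 for IKK_complex-P, otherwise as
  curated), `annotation`. Each term: the published interaction number as
  `id`, `target`, `target_level`, `time_scale` (1–3) and the AND-connected
  `literals` (`component`, `negated`, `threshold`). OR-connected
  alternatives are separate terms sharing a target.
  `lddr::load_full_model()` validates the counts and the ternary set.
- `exclusions_sensitization.txt` — one component name per line: candidates
  excluded from the sensitization-target search
  (template: `exclusions_sensitization.template.txt`).
- `exclusions_carcinogenesis.txt` — likewise for the defect-combination
  search (template: `exclusions_carcinogenesis.template.txt`).

`ddr_core_model.json` (bundled) is the six-component reduced model in the
same format, produced by `lddr::core_model()`.
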