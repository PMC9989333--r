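{
  "_provenance": [
    "Three-population human out-of-Africa demographic history (African,",
    "European, East Asian), using the published 'Low-coverage + exons'",
    "maximum-likelihood parameter estimates of the 1000 Genomes pilot-era",
    "demographic inference: N_A=7310, N_AF=14474, N_B=1861, N_EU0=1032",
    "(growth 0.38%/generation), N_AS0=554 (growth 0.48%/generation),",
    "T_AF=148 kya, T_B (out-of-Africa)=51 kya, T_EU_AS=23 kya, migration",
    "m_AF_B=15e-5, m_AF_EU=2.5e-5, m_AF_AS=0.78e-5, m_EU_AS=3.11e-5;",
    "generation time 25 years. Times below are generations (kya / 25).",
    "Growth epochs state the present-day size; 34041 = 1032*exp(0.0038*920),",
    "45855 = 554*exp(0.0048*920). The EUR branch carries the out-of-Africa",
    "bottleneck population (N_B) between the EUR/EAS split (920) and the",
    "out-of-Africa split (2040)."
  ],
  "species": "human",
  "generation_time_years": 25,
  "time_units": "generations",
  "populations": [
    {
      "id": "AFR",
      "epochs": [
        {"start_time": 0, "size": 14474},
        {"start_time": 5920, "size": 7310}
      ]
    },
    {
      "id": "EUR",
      "epochs": [
        {"start_time": 0, "size": 34041, "growth_rate": 0.0038},
        {"start_time": 920, "size": 1861}
      ]
    },
    {
      "id": "EAS",
      "epochs": [
        {"start_time": 0, "size": 45855, "growth_rate": 0.0048}
      ]
    }
  ],
  "splits": [
    {"time": 2040, "child": "EUR", "parent": "AFR"},
    {"time": 920, "child": "EAS", "parent": "EUR"}
  ],
  "migrations": [
    {"from": "AFR", "to": "EUR", "rate": 15e-5, "start": 920, "end": 2040},
    {"from": "EUR", "to": "AFR", "rate": 15e-5, "start": 920, "end": 2040},
    {"from": "AFR", "to": "EUR", "rate": 2.5e-5, "start": 0, "end": 920},
    {"from": "EUR", "to": "AFR", "rate": 2.5e-5, "start": 0, "end": 920},
    {"from": "AFR", "to": "EAS", "rate": 0.78e-5, "start": 0, "end": 920},
    {"from": "EAS", "to": "AFR", "rate": 0.78e-5, "start": 0, "end": 920},
    {"from": "EUR", "to": "EAS", "rate": 3.11e-5, "start": 0, "end": 920},
    {"from": "EAS", "to": "EUR", "rate": 3.11e-5, "start": 0, "end": 920}
  ]
}
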