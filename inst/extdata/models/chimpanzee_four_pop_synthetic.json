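{
  "_provenance": [
    "Four-subspecies chimpanzee demographic history (Western,",
    "Nigeria-Cameroon, Central, Eastern). SYNTHETIC APPROXIMATION: the exact",
    "MAP parameter values of the published great-ape inference ('model 4A')",
    "are available only in that study's supplement, which could not be",
    "transcribed here. This reconstruction is constrained by (i) the",
    "published present-day sizes quoted in the text (~5,700 Western, ~72,000",
    "Central), (ii) the ((Western,Nigeria-Cameroon),(Central,Eastern))",
    "topology with a deep (~600 kya) Western/Central split, an intermediate",
    "(~250 kya) Western/Nigeria-Cameroon split and a recent (~110 kya)",
    "Central/Eastern split, (iii) published nucleotide-diversity scales",
    "(pi ~ 8e-4 Western, ~1.3e-3 Eastern, ~1.8e-3 Central, giving larger",
    "historical Western sizes with a recent collapse), and (iv) high",
    "migration involving Eastern chimpanzees. Generation time 20 years;",
    "times below are generations (kya * 1000 / 20). Parameters were fixed",
    "once, before any downstream measurement."
  ],
  "species": "chimpanzee",
  "generation_time_years": 20,
  "time_units": "generations",
  "populations": [
    {
      "id": "Western",
      "epochs": [
        {"start_time": 0, "size": 5700},
        {"start_time": 1000, "size": 18500},
        {"start_time": 12500, "size": 16000}
      ]
    },
    {
      "id": "NigeriaCameroon",
      "epochs": [
        {"start_time": 0, "size": 17000}
      ]
    },
    {
      "id": "Central",
      "epochs": [
        {"start_time": 0, "size": 72000},
        {"start_time": 5500, "size": 50000},
        {"start_time": 30000, "size": 19500}
      ]
    },
    {
      "id": "Eastern",
      "epochs": [
        {"start_time": 0, "size": 25000}
      ]
    }
  ],
  "splits": [
    {"time": 12500, "child": "NigeriaCameroon", "parent": "Western"},
    {"time": 5500, "child": "Eastern", "parent": "Central"},
    {"time": 30000, "child": "Western", "parent": "Central"}
  ],
  "migrations": [
    {"from": "Central", "to": "Eastern", "migrants": 4, "start": 0, "end": 5500},
    {"from": "Eastern", "to": "Central", "migrants": 2, "start": 0, "end": 5500},
    {"from": "Western", "to": "NigeriaCameroon", "migrants": 0.2, "start": 0, "end": 12500},
    {"from": "NigeriaCameroon", "to": "Western", "migrants": 0.2, "start": 0, "end": 12500}
  ]
}
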