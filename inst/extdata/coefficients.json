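{
  "schema_version": 1,
  "sets": [
    {
      "model_id": "adjusted_triss",
      "mechanism": "blunt",
      "intercept": -1.64790049,
      "slopes": [0.90535734, -0.07845091, -1.38013670],
      "provenance": "published two-hospital derivation cohort"
    },
    {
      "model_id": "adjusted_triss",
      "mechanism": "penetrating",
      "intercept": -1.29803310,
      "slopes": [0.89538700, -0.09521947, -1.27540759],
      "provenance": "published two-hospital derivation cohort"
    },
    {
      "model_id": "ntriss_like",
      "mechanism": "blunt",
      "intercept": -1.67602650,
      "slopes": [0.61944706, 0.89539814, -0.07289039, -1.33088941],
      "provenance": "published two-hospital derivation cohort"
    },
    {
      "model_id": "ntriss_like",
      "mechanism": "penetrating",
      "intercept": -1.58632944,
      "slopes": [0.58883203, 0.96952677, -0.06659814, -1.00582810],
      "provenance": "published two-hospital derivation cohort"
    },
    {
      "model_id": "triss_spo2",
      "mechanism": "blunt",
      "intercept": -2.97523446,
      "slopes": [0.75773826, 0.58321377, 0.38492625, -0.08441861, -1.59455370],
      "provenance": "published two-hospital derivation cohort"
    },
    {
      "model_id": "triss_spo2",
      "mechanism": "penetrating",
      "intercept": -3.5166820,
      "slopes": [0.8515884, 0.3453793, 1.3098071, -0.1955984, -4.0353761],
      "provenance": "published two-hospital derivation cohort"
    },
    {
      "model_id": "ntriss_like_spo2",
      "mechanism": "blunt",
      "intercept": -2.73634921,
      "slopes": [0.59396868, 0.66226833, 0.56405908, -0.06841853, -1.43274160],
      "provenance": "published two-hospital derivation cohort"
    },
    {
      "model_id": "ntriss_like_spo2",
      "mechanism": "penetrating",
      "intercept": -1.5156694,
      "slopes": [0.1832071, 1.0209288, 1.1288631, -0.1138697, -1.7286860],
      "provenance": "published two-hospital derivation cohort"
    }
  ]
}
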