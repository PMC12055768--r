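window_s: 6
weights:
  Affection: 4.0
  High Validation: 4.0
  Humor: 4.0
  Surprise/Joy: 4.0
  Low Validation: 2.0
  Interest: 2.0
  Neutral: 0.1
  Tense Humor: -1.0
  Tension: -1.0
  Whining: -1.0
  Sadness: -1.0
  Anger: -1.0
  Low Domineering: -1.0
  High Domineering: -1.0
  Belligerence: -2.0
  Defensiveness: -2.0
  Criticism: -2.0
  Stonewalling: -2.0
  Disgust: -3.0
  Contempt: -4.0
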