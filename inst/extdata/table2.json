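{
 "designs": [
  "bht-futility",
  "simon-i",
  "simon-ii",
  "simon-iii"
 ],
 "scenarios": [
  {
   "resp": [
    0.1,
    0.1
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.1 & 0.1"
  },
  {
   "resp": [
    0.2,
    0.2
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.2 & 0.2"
  },
  {
   "resp": [
    0.1,
    0.2
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.1 & 0.2"
  },
  {
   "resp": [
    0.3,
    0.3
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.3 & 0.3"
  },
  {
   "resp": [
    0.4,
    0.4
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.4 & 0.4"
  },
  {
   "resp": [
    0.5,
    0.5
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.5 & 0.5"
  },
  {
   "resp": [
    0.1,
    0.3
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.1 & 0.3"
  },
  {
   "resp": [
    0.1,
    0.4
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.1 & 0.4"
  },
  {
   "resp": [
    0.3,
    0.4
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.3 & 0.4"
  },
  {
   "resp": [
    0.3,
    0.5
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.3 & 0.5"
  },
  {
   "resp": [
    0.4,
    0.5
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.4 & 0.5"
  },
  {
   "resp": [
    0.4,
    0.6
   ],
   "tox": [
    0.0,
    0.0
   ],
   "label": "0.4 & 0.6"
  }
 ],
 "n_reps": 1000
}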