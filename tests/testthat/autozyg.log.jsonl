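{"stage":"read","sample":"SIM001","calls":2988,"stats":{"droppedMissing":0,"droppedHomRef":0,"droppedSymbolic":0,"droppedMalformed":0,"duplicatesRemoved":0}}
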