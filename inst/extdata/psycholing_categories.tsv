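category	words
positive_affect	good|great|happy|love|nice|fun|awesome|excited|glad|hope
negative_affect	bad|sad|angry|hate|awful|terrible|annoyed|upset|worried|cry
social	friend|family|people|talk|party|team|mom|dad|everyone|together
cognitive	think|know|because|reason|maybe|remember|idea|question|wonder|sure
body	sleep|eat|food|tired|pain|head|body|sick|gym|run
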