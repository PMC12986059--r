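{"record":"session","session_id":"S1","month":2,"topic":"anxiety","si_label":"passive","si_discloser":"u1"}
{"record":"session","session_id":"S2","month":7,"topic":"school","si_label":"none","si_discloser":null}
{"record":"visit","session_id":"S1","user_id":"u1","group":"passive_si","gender":"female","race":null,"age":19}
{"record":"visit","session_id":"S1","user_id":"u2","group":"exposed_non_si","gender":null,"race":null,"age":null}
{"record":"visit","session_id":"S2","user_id":"u1","group":"non_exposed_non_si","gender":"male","race":"white","age":24}
{"record":"flag","session_id":"S1","source":"ai","kind":"crisis_flag","t":30}
{"record":"flag","session_id":"S1","source":"moderator","kind":"protocol_question","t":95}
{"record":"message","session_id":"S1","user_id":"u1","role":"participant","index":0,"t":10,"text":"today was hard just feel lonely","despair":6}
{"record":"message","session_id":"S1","user_id":"u2","role":"participant","index":1,"t":20,"text":"same here honestly"}
{"record":"message","session_id":"S1","user_id":"u1","role":"participant","index":2,"t":30,"text":"just wanna disappear","despair":5,"depression":6}
{"record":"message","session_id":"S1","user_id":"u1","role":"participant","index":3,"t":40,"text":"thanks for listening","despair":4}
{"record":"message","session_id":"S1","user_id":"u2","role":"participant","index":4,"t":50,"text":"we are with you"}
{"record":"message","session_id":"S1","user_id":"u2","role":"participant","index":5,"t":60,"text":"stay strong"}
{"record":"message","session_id":"S2","user_id":"u1","role":"participant","index":0,"t":5,"text":"exam stress this week","optimism":2}
{"record":"message","session_id":"S2","user_id":"u1","role":"participant","index":1,"t":15,"text":"trying to plan better","optimism":3}
{"record":"message","session_id":"S2","user_id":"u1","role":"participant","index":2,"t":25,"text":"feeling a bit calmer now","optimism":3}
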