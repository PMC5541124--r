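accession	categories
P63102	binding
P61983	binding
P62260	binding
Q9QXQ0	structural activity;binding
Q9Z1P2	structural activity
P85972	structural activity;binding
P60711	structural activity
P04692	structural activity
P05982	catalytic activity
P70619	catalytic activity
Q64611	catalytic activity
P51583	catalytic activity
B5DFC8	translation;binding
B0BNA7	translation
Q9DBZ5	translation
Q9EPH8	binding;translation
Q9Z1Z3	binding
O55012	binding;transporter
P27615	receptor activity;transporter
P19132	transporter;binding
Q63871	transcription factor activity;binding
Q99P96	enzyme regulator activity;catalytic activity
P31399	catalytic activity;transporter
P29419	catalytic activity;transporter
P11662	catalytic activity
Q63362	catalytic activity
P11247	catalytic activity
P26151	receptor activity;binding
Q9R233	binding
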